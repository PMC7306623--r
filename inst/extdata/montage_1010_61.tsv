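label	x	y	z
Fp1	-0.0954915028125263	0.9510565162951536	0.2938926261462366
Fpz	0	0.9510565162951536	0.3090169943749475
Fp2	0.0954915028125263	0.9510565162951536	0.2938926261462366
AF7	-0.5590169943749475	0.8090169943749475	0.18163563200134025
AF3	-0.3454915028125263	0.8090169943749475	0.4755282581475768
AFz	0	0.8090169943749475	0.5877852522924731
AF4	0.3454915028125263	0.8090169943749475	0.4755282581475768
AF8	0.5590169943749475	0.8090169943749475	0.18163563200134025
F7	-0.7694208842938134	0.5877852522924731	0.25000000000000006
F5	-0.6545084971874737	0.5877852522924731	0.4755282581475768
F3	-0.4755282581475768	0.5877852522924731	0.6545084971874737
F1	-0.24999999999999997	0.5877852522924731	0.7694208842938134
Fz	0	0.5877852522924731	0.8090169943749475
F2	0.24999999999999997	0.5877852522924731	0.7694208842938134
F4	0.4755282581475768	0.5877852522924731	0.6545084971874737
F6	0.6545084971874737	0.5877852522924731	0.4755282581475768
F8	0.7694208842938134	0.5877852522924731	0.25000000000000006
FT7	-0.9045084971874737	0.30901699437494745	0.2938926261462366
FC5	-0.7694208842938134	0.3090169943749474	0.5590169943749475
FC3	-0.5590169943749475	0.3090169943749474	0.7694208842938134
FC1	-0.29389262614623657	0.30901699437494745	0.9045084971874737
FCz	0	0.30901699437494745	0.9510565162951536
FC2	0.29389262614623657	0.30901699437494745	0.9045084971874737
FC4	0.5590169943749475	0.3090169943749474	0.7694208842938134
FC6	0.7694208842938134	0.3090169943749474	0.5590169943749475
FT8	0.9045084971874737	0.30901699437494745	0.2938926261462366
T7	-1	0	6.123233995736766e-17
C5	-0.8090169943749475	0	0.5877852522924731
C3	-0.5877852522924731	0	0.8090169943749475
C1	-0.30901699437494745	0	0.9510565162951536
Cz	0	0	1
C2	0.30901699437494745	0	0.9510565162951536
C4	0.5877852522924731	0	0.8090169943749475
C6	0.8090169943749475	0	0.5877852522924731
T8	1	0	6.123233995736766e-17
TP7	-0.9045084971874737	-0.30901699437494745	0.2938926261462366
CP5	-0.7694208842938134	-0.3090169943749474	0.5590169943749475
CP3	-0.5590169943749475	-0.3090169943749474	0.7694208842938134
CP1	-0.29389262614623657	-0.30901699437494745	0.9045084971874737
CPz	0	-0.30901699437494745	0.9510565162951536
CP2	0.29389262614623657	-0.30901699437494745	0.9045084971874737
CP4	0.5590169943749475	-0.3090169943749474	0.7694208842938134
CP6	0.7694208842938134	-0.3090169943749474	0.5590169943749475
TP8	0.9045084971874737	-0.30901699437494745	0.2938926261462366
P7	-0.7694208842938134	-0.5877852522924731	0.25000000000000006
P5	-0.6545084971874737	-0.5877852522924731	0.4755282581475768
P3	-0.4755282581475768	-0.5877852522924731	0.6545084971874737
P1	-0.24999999999999997	-0.5877852522924731	0.7694208842938134
Pz	0	-0.5877852522924731	0.8090169943749475
P2	0.24999999999999997	-0.5877852522924731	0.7694208842938134
P4	0.4755282581475768	-0.5877852522924731	0.6545084971874737
P6	0.6545084971874737	-0.5877852522924731	0.4755282581475768
P8	0.7694208842938134	-0.5877852522924731	0.25000000000000006
PO7	-0.5590169943749475	-0.8090169943749475	0.18163563200134025
PO3	-0.3454915028125263	-0.8090169943749475	0.4755282581475768
POz	0	-0.8090169943749475	0.5877852522924731
PO4	0.3454915028125263	-0.8090169943749475	0.4755282581475768
PO8	0.5590169943749475	-0.8090169943749475	0.18163563200134025
O1	-0.0954915028125263	-0.9510565162951536	0.2938926261462366
Oz	0	-0.9510565162951536	0.3090169943749475
O2	0.0954915028125263	-0.9510565162951536	0.2938926261462366
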