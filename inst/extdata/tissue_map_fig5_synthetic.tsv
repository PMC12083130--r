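sample_id	tissue
LIV001	Liver
LIV002	Liver
LIV003	Liver
LIV004	Liver
LIV005	Liver
LIV006	Liver
LIV007	Liver
LIV008	Liver
LIV009	Liver
LIV010	Liver
LIV011	Liver
LIV012	Liver
LIV013	Liver
LIV014	Liver
LIV015	Liver
LIV016	Liver
LIV017	Liver
LIV018	Liver
LIV019	Liver
LIV020	Liver
BLD001	Whole Blood
BLD002	Whole Blood
BLD003	Whole Blood
BLD004	Whole Blood
BLD005	Whole Blood
BLD006	Whole Blood
BLD007	Whole Blood
BLD008	Whole Blood
BLD009	Whole Blood
BLD010	Whole Blood
BLD011	Whole Blood
BLD012	Whole Blood
BLD013	Whole Blood
BLD014	Whole Blood
BLD015	Whole Blood
BLD016	Whole Blood
BLD017	Whole Blood
BLD018	Whole Blood
BLD019	Whole Blood
BLD020	Whole Blood
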