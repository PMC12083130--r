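gene	LIV001	LIV002	LIV003	LIV004	LIV005	LIV006	LIV007	LIV008	LIV009	LIV010	LIV011	LIV012	LIV013	LIV014	LIV015	LIV016	LIV017	LIV018	LIV019	LIV020	BLD001	BLD002	BLD003	BLD004	BLD005	BLD006	BLD007	BLD008	BLD009	BLD010	BLD011	BLD012	BLD013	BLD014	BLD015	BLD016	BLD017	BLD018	BLD019	BLD020
F2	112.07	879.425	307.128	145.094	545.454	141.29	281.073	104.205	466.196	297.849	412.638	290.005	205.764	321.912	130.556	343.936	303.649	358.83	345.51	232.29	0.166	0.274	0.334	0.404	0.173	0.523	0.756	0.181	0.155	0.224	0.256	0.316	0.22	0.182	0.289	0.313	0.651	0.578	0.407	0.314
F5	14.051	26.7	37.768	14.8	12.29	31.239	24.426	66.233	30.7	19.44	25.904	21.073	54.811	28.241	26.469	15.051	12.651	14.042	32.559	18.239	4.097	4.24	3.899	3.687	4.206	4.634	2.871	1.998	3.088	7.199	7.26	4.269	7.486	4.635	4.744	2.874	2.415	2.473	3.137	5.431
F9	23.364	48.834	58.766	88.58	92.979	122.043	46.447	35.424	53.574	29.059	84.457	57.077	67.597	125.499	60.418	69.309	58.274	51.472	62.381	60.111	0.176	0.131	0.091	0.137	0.248	0.115	0.103	0.13	0.142	0.182	0.168	0.209	0.095	0.194	0.069	0.059	0.194	0.181	0.186	0.141
PROC	209.119	146.507	116.97	192.584	198.831	220.965	205.365	191.219	116.771	130.412	77.04	117.175	119.207	245.462	120.592	156.824	51.271	234.567	128.227	180.692	0.225	0.644	0.378	0.375	0.567	0.396	0.264	0.532	0.154	0.219	0.468	0.331	0.35	0.523	0.805	0.379	0.257	0.448	0.368	0.598
THBD	10.658	9.96	9.013	6.069	7.932	3.515	8.028	5.378	5.284	12.115	10.138	9.779	7.339	16.117	7.759	9.916	7.193	11.166	6.906	6.664	5.548	8.013	13.991	9.004	11.626	5.865	7.871	3.735	8.075	4.285	8.997	11.251	4.833	9.87	7.203	10.307	8.762	10.972	13.239	5.739
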