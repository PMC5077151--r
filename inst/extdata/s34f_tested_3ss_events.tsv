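event_id	gene_name	event_type	prox_minus3	dist_minus3	prox_fc	prox_p	dist_fc	dist_p	observed
CEP164_se	CEP164	se	T	C	0.40	0.010	1.05	0.600	decreased
FMR1_a3ss	FMR1	a3ss	T	C	0.50	0.020	0.95	0.550	decreased
DEK_se	DEK	se	T	C	0.45	0.010	1.00	0.700	decreased
ZFAND1_se	ZFAND1	se	A	C	1.80	0.015	1.02	0.650	increased
FXR1_se	FXR1	se	C	C	1.60	0.020	0.98	0.600	increased
ATR_se	ATR	se	C	T	0.70	0.040	0.30	0.010	increased
MED15_se	MED15	se	C	A	0.60	0.030	1.00	0.800	increased
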