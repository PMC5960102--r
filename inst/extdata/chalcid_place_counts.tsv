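species	place1	place2	place3	place4
TPRE	580	344	263	124
CFLO	353	509	335	114
CSOL	341	339	398	233
NVIT	37	123	315	836
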