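species	place1
TPRE	490
CFLO	290
CSOL	274
NVIT	33
MDEM	162
AMEL	54
OABI	8
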