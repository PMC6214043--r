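benchmark	method	f_score
sos	BN	0.6154
sos	S-system	0.706
sos	TDSS	0.875
irma_on	HRNN	0.70
irma_on	MMHO-DBN	0.6667
irma_on	TDARACNE	0.6667
irma_on	TDLASSO	0.3077
irma_on	DBmcmc	0.3333
irma_on	DBN-ZC	0.4615
irma_off	MMHO-DBN	0.363
irma_off	TDARACNE	0.2000
irma_off	TDLASSO	0.1667
irma_off	DBmcmc	0.1407
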