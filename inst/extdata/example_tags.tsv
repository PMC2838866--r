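scan	mp	tag	mq	score	validity	identification
1616	1001.540	APAJG	146.112	8.7	correct	K.RVFNVLTGDAPAIGK.V
1629	1069.550	VJCJQPK	44.049	5.3	not_available	NA
1630	897.447	QEKEVAAVJ	128.105	14.8	incorrect	K.KLVAAVEKEGAGFDLGAYR.D
1635	980.533	EJVQ	146.109	5.3	incorrect	K.MIHFVPRDNIVQK.A
1636	358.233	DGJMVJA	137.071	22.1	correct	R.HALVMLGDALR.H
1640	1219.610	TSSMG	589.296	7.6	correct	R.NYAQLGMSSTPFYQSHGVASK.S
1641	830.437	TJFGA	146.113	11.5	correct	K.IFTTRPDTLFGAK.F
1643	888.524	AGDGAK	147.079	10.4	correct	R.FKAGDGAIVNGIAFR.S
1644	128.096	JFDVJA	271.174	19.3	correct	K.KLFDVLAPR.Y
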