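gene	variant	type	size	active	stop_domains
TuA3-385	TuA3-385a	m	385	FALSE	repetitive
TuA3-385	TuA3-385b	m	385	FALSE	repetitive
TuA3-391	TuA3-373	m	373	FALSE	repetitive
TuA3-391	TuA3-391	m	391	FALSE	repetitive
TuA3-391	TuA3-392	m	392	FALSE	C-terminal I
TuA3-397	TuA3-397a	m	397	FALSE	repetitive
TuA3-397	TuA3-397b	m	397	TRUE	none
TuA3-400	TuA3-400	m	400	TRUE	none
TuA3-400	TuA3-402	m	402	FALSE	C-terminal II
TuA3-460	TuA3-460	s	460	FALSE	repetitive;C-terminal I
TuA3-460	TuA3-463	s	463	FALSE	repetitive;C-terminal I
TuA3-460	TuA3-474	s	474	FALSE	repetitive;C-terminal I
TuA3-502	TuA3-495	i	495	FALSE	repetitive
TuA3-502	TuA3-498	i	498	TRUE	none
TuA3-502	TuA3-502a	i	502	TRUE	none
TuA3-502	TuA3-502b	i	502	FALSE	repetitive
TuA3-502	TuA3-502c	i	502	TRUE	none
TuA3-502	TuA3-502d	i	502	FALSE	repetitive
TuA3-502	TuA3-520	i	520	TRUE	none
TuA3-502	TuA3-590	i	590	FALSE	repetitive
TuA3-502	TuA3-593	i	593	FALSE	repetitive
TuA3-538	TuA3-535	i	535	TRUE	none
TuA3-538	TuA3-538a	i	538	TRUE	none
TuA3-538	TuA3-538b	i	538	TRUE	none
TuA3-538	TuA3-538c	i	538	TRUE	none
TuA3-538	TuA3-538d	i	538	FALSE	repetitive
TuA3-538	TuA3-538e	i	538	TRUE	none
TuA3-538	TuA3-657	i	657	TRUE	none
TuA3-576	TuA3-406	i	406	FALSE	repetitive
TuA3-576	TuA3-555	i	555	TRUE	none
TuA3-576	TuA3-576a	i	576	TRUE	none
TuA3-576	TuA3-576b	i	576	TRUE	none
TuA3-576	TuA3-576c	i	576	TRUE	none
TuA3-576	TuA3-576d	i	576	FALSE	C-terminal II
TuA3-576	TuA3-576e	i	576	TRUE	none
TuA3-576	TuA3-579a	i	579	TRUE	none
TuA3-576	TuA3-579b	i	579	TRUE	none
TuA3-576	TuA3-597	i	597	TRUE	none
TuA3-576	TuA3-669	i	669	TRUE	none
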