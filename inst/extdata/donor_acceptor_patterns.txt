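# Donor/acceptor substructure pattern library.
# One pattern per line: <pattern><TAB><role><TAB><label>.
# The first atom of each pattern is taken as the attachment atom for
# donor-acceptor distance measurements. Supported pattern syntax is the
# SMARTS subset documented in ?match_pattern.
[NX3;H2]	donor	primary_amine
[NX3;H1]([#6])[#6]	donor	secondary_amine
[NX3;H0]([#6])([#6])[#6]	donor	tertiary_amine
[OX2;H1]	donor	hydroxy
[OX2;H0]([#6])[#6]	donor	ether_alkoxy
[SX2;H0]([#6])[#6]	donor	thioether
[N+](=[OX1])[O-]	acceptor	nitro
[CX2]#[NX1]	acceptor	cyano
[CX3]=[OX1]	acceptor	carbonyl
[SX4](=[OX1])=[OX1]	acceptor	sulfonyl
[n+]	acceptor	pyridinium
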