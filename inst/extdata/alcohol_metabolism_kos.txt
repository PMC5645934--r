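# Alcohol-metabolism KO panel (configuration; edit to analyze another set)
K00001	alcohol dehydrogenase
K00002	alcohol dehydrogenase (NADP+)
K00114	alcohol dehydrogenase (cytochrome c)
K00121	S-(hydroxymethyl)glutathione dehydrogenase / class III ADH
K00128	aldehyde dehydrogenase (NAD+)
K00129	aldehyde dehydrogenase (NAD(P)+)
K00132	acetaldehyde dehydrogenase (acetylating)
K00138	aldehyde dehydrogenase
K00149	aldehyde dehydrogenase family 9
K01895	acetyl-CoA synthetase
K04072	acetaldehyde dehydrogenase / alcohol dehydrogenase (adhE)
K04073	acetaldehyde dehydrogenase (mhpF)
K13951	alcohol dehydrogenase 1/7
K13952	alcohol dehydrogenase 6
K13953	alcohol dehydrogenase (adhP)
K13954	NADP-dependent alcohol dehydrogenase (yqhD)
K13980	alcohol dehydrogenase (adhB)
K14028	methanol dehydrogenase large subunit
K18857	alcohol dehydrogenase class-P
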