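protein_id	position	labels
Q16778	6	acetylation,crotonylation
Q16778	12	acetylation,crotonylation
Q16778	13	acetylation,crotonylation
Q16778	16	acetylation,crotonylation
Q16778	17	acetylation,crotonylation
Q16778	21	acetylation,crotonylation
Q16778	24	acetylation,crotonylation
Q16778	25	
Q16778	28	
Q16778	29	
Q16778	31	
Q16778	35	crotonylation
Q16778	44	
Q16778	47	methylation
Q16778	58	methylation
Q16778	86	acetylation,methylation
Q16778	109	
Q16778	117	acetylation
Q16778	121	acetylation,succinylation
Q16778	126	succinylation
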