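receptor	system	class
5HT1A	serotonin	inhibitory
5HT1B	serotonin	inhibitory
5HT2A	serotonin	excitatory
5HT4	serotonin	excitatory
5HT6	serotonin	excitatory
5HTT	serotonin	inhibitory
A4B2	acetylcholine	excitatory
M1	acetylcholine	excitatory
VAChT	acetylcholine	excitatory
CB1	cannabinoid	inhibitory
D1	dopamine	excitatory
D2	dopamine	inhibitory
DAT	dopamine	inhibitory
GABAa	GABA	inhibitory
H3	histamine	inhibitory
mGluR5	glutamate	excitatory
NMDA	glutamate	excitatory
MOR	opioid	inhibitory
NET	norepinephrine	excitatory
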