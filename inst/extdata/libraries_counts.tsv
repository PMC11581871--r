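species	ena_run	raw_reads	preprocessed_reads
A. thaliana	SRR22559142	20248052	19336553
A. thaliana	SRR22559143	20784415	19864492
A. thaliana	SRR22559144	22169416	21188340
S. lycopersicum	SRR25558913	43307357	41602968
S. lycopersicum	SRR25558914	41684242	40278306
S. lycopersicum	SRR25558915	49831874	47801733
C. campestris	SRR12763776	15454773	14613644
C. campestris	SRR12763787	15497676	14578626
C. campestris	SRR12763788	15864650	14978212
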