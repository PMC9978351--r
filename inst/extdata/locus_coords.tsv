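name	value	strand	note
ssr7036_tss	32177	+	transcriptional start site of the ssr7036 mRNA precursor (TU7029)
asrna1_tss	32481	-	transcriptional start site of asRNA1 (TU7031); native transcript is 153 nt
asrna1_3p	32329	-	3'-most nucleotide of the 153-nt asRNA1
substrate_5p	32483	-	5'-most templated nucleotide of the in vitro asRNA1 substrate (two nt upstream of the TSS)
orf_start	32289	+	first nucleotide of the ssr7036 reading frame
orf_end	32483	+	last nucleotide of the ssr7036 stop codon
cleavage_upstream	32426	-	mapped RNase E cleavage site in asRNA1
cleavage_downstream	32418	-	mapped RNase E cleavage site in asRNA1
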