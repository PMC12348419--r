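!gaf-version: 2.2
!generated-by: transpred synthetic fixture (not real annotation data)
UniProtKB	P00001	AAT1	enables	GO:0015171	GO_REF:0000001	IDA		F	Amino acid transporter 1	AAT1	protein	taxon:3702	20250101	UniProt
UniProtKB	P00002	AAT2	enables	GO:0015171	GO_REF:0000001	IMP		F	Amino acid transporter 2	AAT2	protein	taxon:3702	20250101	UniProt
UniProtKB	P00003	AAT3	enables	GO:0015173	GO_REF:0000001	IDA		F	Aromatic AA transporter	AAT3	protein	taxon:3702	20250101	UniProt
UniProtKB	P00004	AAT4	enables	GO:0015171	GO_REF:0000001	TAS		F	Amino acid transporter 4	AAT4	protein	taxon:3702	20250101	UniProt
UniProtKB	P00005	SUG1	enables	GO:0051119	GO_REF:0000001	IDA		F	Sugar transporter 1	SUG1	protein	taxon:3702	20250101	UniProt
UniProtKB	P00006	SUG2	enables	GO:0005351	GO_REF:0000001	IMP		F	Sugar symporter 2	SUG2	protein	taxon:3702	20250101	UniProt
UniProtKB	P00007	SUG3	enables	GO:0051119	GO_REF:0000001	IEP		F	Sugar transporter 3	SUG3	protein	taxon:3702	20250101	UniProt
UniProtKB	P00008	SUG4	enables	GO:0051119	GO_REF:0000001	IEA		F	Sugar transporter 4 (electronic only)	SUG4	protein	taxon:3702	20250101	InterPro
UniProtKB	P00009	DUAL1	enables	GO:0015171	GO_REF:0000001	IDA		F	Dual-substrate transporter	DUAL1	protein	taxon:3702	20250101	UniProt
UniProtKB	P00009	DUAL1	enables	GO:0051119	GO_REF:0000001	IDA		F	Dual-substrate transporter	DUAL1	protein	taxon:3702	20250101	UniProt
UniProtKB	P00010	GLR33	enables	GO:0004970	GO_REF:0000001	IDA		F	Glutamate-gated channel (faulty is_a case)	GLR33	protein	taxon:3702	20250101	UniProt
UniProtKB	P00011	FRAG1	enables	GO:0015171	GO_REF:0000001	IDA		F	Fragment protein	FRAG1	protein	taxon:3702	20250101	UniProt
UniProtKB	P00012	NOTS1	NOT|enables	GO:0051119	GO_REF:0000001	IDA		F	Negated sugar annotation	NOTS1	protein	taxon:3702	20250101	UniProt
UniProtKB	P00013	UNREV	enables	GO:0051119	GO_REF:0000001	IDA		F	Unreviewed sugar transporter	UNREV	protein	taxon:3702	20250101	UniProt
UniProtKB	P00014	XSEQ1	enables	GO:0015171	GO_REF:0000001	IDA		F	Has nonstandard residues	XSEQ1	protein	taxon:3702	20250101	UniProt
UniProtKB	P00015	MEMB1	located_in	GO:0016020	GO_REF:0000001	IDA		C	Membrane protein	MEMB1	protein	taxon:3702	20250101	UniProt
UniProtKB	P00016	IEA2	enables	GO:0015171	GO_REF:0000001	IEA		F	Electronic amino acid annotation	IEA2	protein	taxon:3702	20250101	InterPro
UniProtKB	P00017	SYM1	enables	GO:0015293	GO_REF:0000001	IDA		F	Symporter, neither class	SYM1	protein	taxon:3702	20250101	UniProt
UniProtKB	P00018	SUG5	enables	GO:0005351	GO_REF:0000001	HDA		F	Sugar symporter 5	SUG5	protein	taxon:3702	20250101	UniProt
UniProtKB	P00019	UNK1	enables	GO:0099998	GO_REF:0000001	IDA		F	Annotation to unknown term	UNK1	protein	taxon:3702	20250101	UniProt
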