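pul_id	genome_id	contig_id	start	end	n_genes	n_seeds	simple	signature
demo_genes_contig_1_pul1	demo_genes	contig_1	10001	17900	8	1	FALSE	GH43-GH10 | GH67-GH35-susC-susD-unc-GH10
demo_genes_contig_2_pul1	demo_genes	contig_2	8001	9900	2	1	TRUE	susC-susD
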