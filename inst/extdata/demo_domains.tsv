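protein_id	source	label	evalue	bitscore	ali_length	hmm_coverage	env_start	env_end
demoMAG_contig_1_g01	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_1_g02	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_1_g03	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_1_g04	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_1_g05	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_1_g06	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_1_g07	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_1_g08	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_1_g09	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_1_g10	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_1_g11	cazy	GH43	1e-30	150	200	0.9	1	200
demoMAG_contig_1_g12	cazy	GH10	1e-30	150	200	0.9	1	200
demoMAG_contig_1_g13	cazy	GH67	1e-30	150	200	0.9	1	200
demoMAG_contig_1_g14	cazy	GH35	1e-30	150	200	0.9	1	200
demoMAG_contig_1_g15	pfam	PF00593	1e-30	250	200	0.9	1	200
demoMAG_contig_1_g16	pfam	PF07980	1e-30	220	200	0.9	1	200
demoMAG_contig_1_g17	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_1_g18	cazy	GH10	1e-30	150	200	0.9	1	200
demoMAG_contig_1_g19	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_1_g20	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_1_g21	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_1_g22	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_1_g23	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_1_g24	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_1_g25	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_1_g26	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_1_g27	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_1_g28	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_2_g01	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_2_g02	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_2_g03	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_2_g04	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_2_g05	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_2_g06	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_2_g07	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_2_g08	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_2_g09	pfam	PF00593	1e-30	250	200	0.9	1	200
demoMAG_contig_2_g10	pfam	PF07980	1e-30	220	200	0.9	1	200
demoMAG_contig_2_g11	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_2_g12	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_2_g13	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_2_g14	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_2_g15	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_2_g16	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_2_g17	pfam	PF00077	1e-30	60	200	0.9	1	200
demoMAG_contig_2_g18	pfam	PF00077	1e-30	60	200	0.9	1	200
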