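trait	accessory_class	defence_side	putative_function
rm_hsdR	rm_system	phage_defence	Type I RM restriction subunit (HsdR)
rm_hsdM	rm_system	phage_defence	Type I RM methyltransferase subunit (HsdM)
rm_hsdS	rm_system	phage_defence	Type I RM DNA specificity subunit (HsdS)
rm_type3	rm_system	phage_defence	Type III restriction-modification subunit
ta_toxin	ta_system	phage_defence	Toxin component of a toxin-antitoxin system
ta_antitoxin	ta_system	anti_phage_defence	Antitoxin component of a TA system
reverse_transcriptase_maturase	diversity_generating	none	Group II intron reverse transcriptase/maturase
avd_dgr	diversity_generating	none	Avd accessory protein of a diversity-generating retroelement
anti_crispr	anti_phage_defence	anti_phage_defence	Anti-CRISPR protein
restriction_alleviation	anti_phage_defence	anti_phage_defence	Lar-like restriction alleviation protein
mom_modification	anti_phage_defence	anti_phage_defence	Mom-like DNA modification protein
darB_antirestriction	anti_phage_defence	anti_phage_defence	DarB-like antirestriction protein
amidoligase	host_adaptation	none	Amidoligase enzyme (cell-wall modification)
ggct	host_adaptation	none	Gamma-glutamyl cyclotransferase
paps_reductase	host_adaptation	none	Phosphoadenosine phosphosulfate reductase
dextransucrase	host_adaptation	none	Dextransucrase (host metabolism)
haemolysin	host_adaptation	none	Putative haemolysin (host fitness/cell lysis)
cm_phosphotransferase	host_adaptation	none	Chloramphenicol phosphotransferase-like protein
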