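column	type	description
spectrum_id	character	opaque unique spectrum token
run_id	character	LC-MS/MS run identifier
plex_id	character	TMT plex identifier
fraction_id	character	fraction identifier
charge	integer	precursor charge, 1-6
precursor_mh	numeric	precursor MH+ mass in Da
mass_error_ppm	numeric	signed precursor mass error in ppm
score	numeric	identification score, higher is better
delta_rank_score	numeric	score(rank1) - score(rank2), >= 0
delta_fr_score	numeric	forward-minus-reverse score; negative flags likely false match
bcs	numeric	backbone cleavage score (sequence coverage metric), >= 0
spi_pct	numeric	scored peak intensity percentage, 0-100
sequence	character	peptide sequence, upper-case; modified lysine rendered lowercase k
modifications	character	";"-joined "pos:type" pairs, 1-based peptide positions; empty if none
loc_top_score	numeric	identification score of the best site localization (NA if unmodified)
loc_second_score	numeric	score of the runner-up localization (NA if single candidate)
is_decoy	logical	TRUE for decoy-database matches
class_label	character	canonical | nuORF:<category> | variant | contaminant
purity_pct	numeric	precursor isolation purity, 0-100
tmt_labeled	logical	TRUE when the peptide carries a TMT label
proteins	character	";"-joined candidate protein accessions
reporter_<channel>	numeric	one column per plex channel; non-negative reporter intensity (optional)
tag_length	integer	sequence tag length from spectral quality assessment (optional)
is_human	logical	species annotation used by contaminant removal (optional)
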