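accession	species	taxonomic_order	assembly_level	submission_date	submitter_institute	submitter_country	is_reference	sra_linked
GCA_021130785.2	Homalodisca vitripennis	Hemiptera	chromosome	2021-12-15	Agricultural Research Institute	United States	TRUE	TRUE
GCA_019364655.1	Homalodisca vitripennis	Hemiptera	scaffold	2021-07-20	University Genome Institute	United States	FALSE	TRUE
GCA_905475345.1	Vespula vulgaris	Hymenoptera	chromosome	2021-04-23	Wellcome Sanger Institute	United Kingdom	TRUE	TRUE
GCA_014466185.1	Vespula vulgaris	Hymenoptera	chromosome	2020-09-04	National Sequencing Centre	New Zealand	FALSE	TRUE
GCA_905147795.1	Pieris rapae	Lepidoptera	chromosome	2021-02-11	Wellcome Sanger Institute	United Kingdom	TRUE	TRUE
GCA_001856805.1	Pieris rapae	Lepidoptera	scaffold	2016-10-05	University Genome Institute	United States	FALSE	TRUE
GCA_013339765.2	Haemaphysalis longicornis	Ixodida	chromosome	2020-06-30	University Genome Institute	China	TRUE	TRUE
GCA_008122185.1	Haemaphysalis longicornis	Ixodida	scaffold	2019-08-12	National Sequencing Centre	New Zealand	FALSE	TRUE
GCA_003402655.1	Harmonia axyridis	Coleoptera	scaffold	2018-08-01	University Genome Institute	Japan	TRUE	FALSE
GCA_914767665.1	Harmonia axyridis	Coleoptera	chromosome	2021-11-09	Wellcome Sanger Institute	United Kingdom	FALSE	TRUE
GCA_024506325.2	Diaphorina citri	Hemiptera	chromosome	2022-08-16	Agricultural Research Institute	United States	TRUE	TRUE
GCA_024506275.2	Diaphorina citri	Hemiptera	chromosome	2022-08-16	Agricultural Research Institute	United States	FALSE	TRUE
GCA_024506315.2	Diaphorina citri	Hemiptera	chromosome	2022-08-16	Agricultural Research Institute	United States	FALSE	TRUE
GCA_905340365.1	Vespula germanica	Hymenoptera	chromosome	2021-03-17	Wellcome Sanger Institute	United Kingdom	TRUE	TRUE
GCA_014466195.1	Vespula germanica	Hymenoptera	chromosome	2020-09-04	National Sequencing Centre	New Zealand	FALSE	TRUE
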