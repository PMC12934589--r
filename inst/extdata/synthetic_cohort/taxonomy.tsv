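taxon_id	phylum	genus	species
taxon_001	Phylum_A	Genus_001	taxon_001
taxon_002	Phylum_A	Genus_001	taxon_002
taxon_003	Phylum_A	Genus_001	taxon_003
taxon_004	Phylum_B	Genus_002	taxon_004
taxon_005	Phylum_B	Genus_002	taxon_005
taxon_006	Phylum_B	Genus_002	taxon_006
taxon_007	Phylum_C	Genus_003	taxon_007
taxon_008	Phylum_C	Genus_003	taxon_008
taxon_009	Phylum_C	Genus_003	taxon_009
taxon_010	Phylum_D	Genus_004	taxon_010
taxon_011	Phylum_D	Genus_004	taxon_011
taxon_012	Phylum_D	Genus_004	taxon_012
taxon_013	Phylum_E	Genus_005	taxon_013
taxon_014	Phylum_E	Genus_005	taxon_014
taxon_015	Phylum_E	Genus_005	taxon_015
taxon_016	Phylum_F	Genus_006	taxon_016
taxon_017	Phylum_F	Genus_006	taxon_017
taxon_018	Phylum_F	Genus_006	taxon_018
taxon_019	Phylum_G	Genus_007	taxon_019
taxon_020	Phylum_G	Genus_007	taxon_020
taxon_021	Phylum_G	Genus_007	taxon_021
taxon_022	Phylum_H	Genus_008	taxon_022
taxon_023	Phylum_H	Genus_008	taxon_023
taxon_024	Phylum_H	Genus_008	taxon_024
taxon_025	Phylum_A	Genus_009	taxon_025
taxon_026	Phylum_A	Genus_009	taxon_026
taxon_027	Phylum_A	Genus_009	taxon_027
taxon_028	Phylum_B	Genus_010	taxon_028
taxon_029	Phylum_B	Genus_010	taxon_029
taxon_030	Phylum_B	Genus_010	taxon_030
taxon_031	Phylum_C	Genus_011	taxon_031
taxon_032	Phylum_C	Genus_011	taxon_032
taxon_033	Phylum_C	Genus_011	taxon_033
taxon_034	Phylum_D	Genus_012	taxon_034
taxon_035	Phylum_D	Genus_012	taxon_035
taxon_036	Phylum_D	Genus_012	taxon_036
taxon_037	Phylum_E	Genus_013	taxon_037
taxon_038	Phylum_E	Genus_013	taxon_038
taxon_039	Phylum_E	Genus_013	taxon_039
taxon_040	Phylum_F	Genus_014	taxon_040
taxon_041	Phylum_F	Genus_014	taxon_041
taxon_042	Phylum_F	Genus_014	taxon_042
taxon_043	Phylum_G	Genus_015	taxon_043
taxon_044	Phylum_G	Genus_015	taxon_044
taxon_045	Phylum_G	Genus_015	taxon_045
taxon_046	Phylum_H	Genus_016	taxon_046
taxon_047	Phylum_H	Genus_016	taxon_047
taxon_048	Phylum_H	Genus_016	taxon_048
taxon_049	Phylum_A	Genus_017	taxon_049
taxon_050	Phylum_A	Genus_017	taxon_050
taxon_051	Phylum_A	Genus_017	taxon_051
taxon_052	Phylum_B	Genus_018	taxon_052
taxon_053	Phylum_B	Genus_018	taxon_053
taxon_054	Phylum_B	Genus_018	taxon_054
taxon_055	Phylum_C	Genus_019	taxon_055
taxon_056	Phylum_C	Genus_019	taxon_056
taxon_057	Phylum_C	Genus_019	taxon_057
taxon_058	Phylum_D	Genus_020	taxon_058
taxon_059	Phylum_D	Genus_020	taxon_059
taxon_060	Phylum_D	Genus_020	taxon_060
taxon_061	Phylum_E	Genus_021	taxon_061
taxon_062	Phylum_E	Genus_021	taxon_062
taxon_063	Phylum_E	Genus_021	taxon_063
taxon_064	Phylum_F	Genus_022	taxon_064
taxon_065	Phylum_F	Genus_022	taxon_065
taxon_066	Phylum_F	Genus_022	taxon_066
taxon_067	Phylum_G	Genus_023	taxon_067
taxon_068	Phylum_G	Genus_023	taxon_068
taxon_069	Phylum_G	Genus_023	taxon_069
taxon_070	Phylum_H	Genus_024	taxon_070
taxon_071	Phylum_H	Genus_024	taxon_071
taxon_072	Phylum_H	Genus_024	taxon_072
taxon_073	Phylum_A	Genus_025	taxon_073
taxon_074	Phylum_A	Genus_025	taxon_074
taxon_075	Phylum_A	Genus_025	taxon_075
taxon_076	Phylum_B	Genus_026	taxon_076
taxon_077	Phylum_B	Genus_026	taxon_077
taxon_078	Phylum_B	Genus_026	taxon_078
taxon_079	Phylum_C	Genus_027	taxon_079
taxon_080	Phylum_C	Genus_027	taxon_080
taxon_081	Phylum_C	Genus_027	taxon_081
taxon_082	Phylum_D	Genus_028	taxon_082
taxon_083	Phylum_D	Genus_028	taxon_083
taxon_084	Phylum_D	Genus_028	taxon_084
taxon_085	Phylum_E	Genus_029	taxon_085
taxon_086	Phylum_E	Genus_029	taxon_086
taxon_087	Phylum_E	Genus_029	taxon_087
taxon_088	Phylum_F	Genus_030	taxon_088
taxon_089	Phylum_F	Genus_030	taxon_089
taxon_090	Phylum_F	Genus_030	taxon_090
taxon_091	Phylum_G	Genus_031	taxon_091
taxon_092	Phylum_G	Genus_031	taxon_092
taxon_093	Phylum_G	Genus_031	taxon_093
taxon_094	Phylum_H	Genus_032	taxon_094
taxon_095	Phylum_H	Genus_032	taxon_095
taxon_096	Phylum_H	Genus_032	taxon_096
taxon_097	Phylum_A	Genus_033	taxon_097
taxon_098	Phylum_A	Genus_033	taxon_098
taxon_099	Phylum_A	Genus_033	taxon_099
taxon_100	Phylum_B	Genus_034	taxon_100
contam_01	Phylum_contaminant	Genus_contaminant	contam_01
contam_02	Phylum_contaminant	Genus_contaminant	contam_02
contam_03	Phylum_contaminant	Genus_contaminant	contam_03
contam_04	Phylum_contaminant	Genus_contaminant	contam_04
contam_05	Phylum_contaminant	Genus_contaminant	contam_05
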