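F001	F001_p1	0	0	1	0
F001	F001_p2	0	0	2	0
F001	F001_s1	F001_p1	F001_p2	0	1
F001	F001_s2	F001_p1	F001_p2	0	1
F002	F002_p1	0	0	1	0
F002	F002_p2	0	0	2	0
F002	F002_s1	F002_p1	F002_p2	0	1
F002	F002_s2	F002_p1	F002_p2	0	1
F003	F003_p1	0	0	1	0
F003	F003_p2	0	0	2	0
F003	F003_s1	F003_p1	F003_p2	0	1
F003	F003_s2	F003_p1	F003_p2	0	1
F004	F004_p1	0	0	1	0
F004	F004_p2	0	0	2	0
F004	F004_s1	F004_p1	F004_p2	0	1
F004	F004_s2	F004_p1	F004_p2	0	1
F005	F005_p1	0	0	1	0
F005	F005_p2	0	0	2	0
F005	F005_s1	F005_p1	F005_p2	0	1
F005	F005_s2	F005_p1	F005_p2	0	1
F006	F006_p1	0	0	1	0
F006	F006_p2	0	0	2	0
F006	F006_s1	F006_p1	F006_p2	0	1
F006	F006_s2	F006_p1	F006_p2	0	1
F007	F007_p1	0	0	1	0
F007	F007_p2	0	0	2	0
F007	F007_s1	F007_p1	F007_p2	0	1
F007	F007_s2	F007_p1	F007_p2	0	1
F008	F008_p1	0	0	1	0
F008	F008_p2	0	0	2	0
F008	F008_s1	F008_p1	F008_p2	0	1
F008	F008_s2	F008_p1	F008_p2	0	1
F009	F009_p1	0	0	1	0
F009	F009_p2	0	0	2	0
F009	F009_s1	F009_p1	F009_p2	0	1
F009	F009_s2	F009_p1	F009_p2	0	1
F010	F010_p1	0	0	1	0
F010	F010_p2	0	0	2	0
F010	F010_s1	F010_p1	F010_p2	0	1
F010	F010_s2	F010_p1	F010_p2	0	1
F011	F011_p1	0	0	1	0
F011	F011_p2	0	0	2	0
F011	F011_s1	F011_p1	F011_p2	0	1
F011	F011_s2	F011_p1	F011_p2	0	1
F012	F012_p1	0	0	1	0
F012	F012_p2	0	0	2	0
F012	F012_s1	F012_p1	F012_p2	0	1
F012	F012_s2	F012_p1	F012_p2	0	1
F013	F013_p1	0	0	1	0
F013	F013_p2	0	0	2	0
F013	F013_s1	F013_p1	F013_p2	0	1
F013	F013_s2	F013_p1	F013_p2	0	1
F014	F014_p1	0	0	1	0
F014	F014_p2	0	0	2	0
F014	F014_s1	F014_p1	F014_p2	0	1
F014	F014_s2	F014_p1	F014_p2	0	1
F015	F015_p1	0	0	1	0
F015	F015_p2	0	0	2	0
F015	F015_s1	F015_p1	F015_p2	0	1
F015	F015_s2	F015_p1	F015_p2	0	1
F016	F016_p1	0	0	1	0
F016	F016_p2	0	0	2	0
F016	F016_s1	F016_p1	F016_p2	0	1
F016	F016_s2	F016_p1	F016_p2	0	1
F017	F017_p1	0	0	1	0
F017	F017_p2	0	0	2	0
F017	F017_s1	F017_p1	F017_p2	0	1
F017	F017_s2	F017_p1	F017_p2	0	1
F018	F018_p1	0	0	1	0
F018	F018_p2	0	0	2	0
F018	F018_s1	F018_p1	F018_p2	0	1
F018	F018_s2	F018_p1	F018_p2	0	1
F019	F019_p1	0	0	1	0
F019	F019_p2	0	0	2	0
F019	F019_s1	F019_p1	F019_p2	0	1
F019	F019_s2	F019_p1	F019_p2	0	1
F020	F020_p1	0	0	1	0
F020	F020_p2	0	0	2	0
F020	F020_s1	F020_p1	F020_p2	0	1
F020	F020_s2	F020_p1	F020_p2	0	1
F021	F021_p1	0	0	1	0
F021	F021_p2	0	0	2	0
F021	F021_s1	F021_p1	F021_p2	0	1
F021	F021_s2	F021_p1	F021_p2	0	1
F022	F022_p1	0	0	1	0
F022	F022_p2	0	0	2	0
F022	F022_s1	F022_p1	F022_p2	0	1
F022	F022_s2	F022_p1	F022_p2	0	1
F023	F023_p1	0	0	1	0
F023	F023_p2	0	0	2	0
F023	F023_s1	F023_p1	F023_p2	0	1
F023	F023_s2	F023_p1	F023_p2	0	1
F024	F024_p1	0	0	1	0
F024	F024_p2	0	0	2	0
F024	F024_s1	F024_p1	F024_p2	0	1
F024	F024_s2	F024_p1	F024_p2	0	1
F025	F025_p1	0	0	1	0
F025	F025_p2	0	0	2	0
F025	F025_s1	F025_p1	F025_p2	0	1
F025	F025_s2	F025_p1	F025_p2	0	1
F026	F026_p1	0	0	1	0
F026	F026_p2	0	0	2	0
F026	F026_s1	F026_p1	F026_p2	0	1
F026	F026_s2	F026_p1	F026_p2	0	1
F027	F027_p1	0	0	1	0
F027	F027_p2	0	0	2	0
F027	F027_s1	F027_p1	F027_p2	0	1
F027	F027_s2	F027_p1	F027_p2	0	1
F028	F028_p1	0	0	1	0
F028	F028_p2	0	0	2	0
F028	F028_s1	F028_p1	F028_p2	0	1
F028	F028_s2	F028_p1	F028_p2	0	1
F029	F029_p1	0	0	1	0
F029	F029_p2	0	0	2	0
F029	F029_s1	F029_p1	F029_p2	0	1
F029	F029_s2	F029_p1	F029_p2	0	1
F030	F030_p1	0	0	1	0
F030	F030_p2	0	0	2	0
F030	F030_s1	F030_p1	F030_p2	0	1
F030	F030_s2	F030_p1	F030_p2	0	1
F031	F031_p1	0	0	1	0
F031	F031_p2	0	0	2	0
F031	F031_s1	F031_p1	F031_p2	0	1
F031	F031_s2	F031_p1	F031_p2	0	1
F032	F032_p1	0	0	1	0
F032	F032_p2	0	0	2	0
F032	F032_s1	F032_p1	F032_p2	0	1
F032	F032_s2	F032_p1	F032_p2	0	1
F033	F033_p1	0	0	1	0
F033	F033_p2	0	0	2	0
F033	F033_s1	F033_p1	F033_p2	0	1
F033	F033_s2	F033_p1	F033_p2	0	1
F034	F034_p1	0	0	1	0
F034	F034_p2	0	0	2	0
F034	F034_s1	F034_p1	F034_p2	0	1
F034	F034_s2	F034_p1	F034_p2	0	1
F035	F035_p1	0	0	1	0
F035	F035_p2	0	0	2	0
F035	F035_s1	F035_p1	F035_p2	0	1
F035	F035_s2	F035_p1	F035_p2	0	1
F036	F036_p1	0	0	1	0
F036	F036_p2	0	0	2	0
F036	F036_s1	F036_p1	F036_p2	0	1
F036	F036_s2	F036_p1	F036_p2	0	1
F037	F037_p1	0	0	1	0
F037	F037_p2	0	0	2	0
F037	F037_s1	F037_p1	F037_p2	0	1
F037	F037_s2	F037_p1	F037_p2	0	1
F038	F038_p1	0	0	1	0
F038	F038_p2	0	0	2	0
F038	F038_s1	F038_p1	F038_p2	0	1
F038	F038_s2	F038_p1	F038_p2	0	1
F039	F039_p1	0	0	1	0
F039	F039_p2	0	0	2	0
F039	F039_s1	F039_p1	F039_p2	0	1
F039	F039_s2	F039_p1	F039_p2	0	1
F040	F040_p1	0	0	1	1
F040	F040_c1	F040_p1	0	0	1
F041	F041_p1	0	0	1	1
F041	F041_c1	F041_p1	0	0	1
F042	F042_p1	0	0	1	1
F042	F042_c1	F042_p1	0	0	1
F043	F043_p1	0	0	1	1
F043	F043_c1	F043_p1	0	0	1
F044	F044_p1	0	0	1	1
F044	F044_c1	F044_p1	0	0	1
F045	F045_p1	0	0	1	1
F045	F045_c1	F045_p1	0	0	1
F046	F046_p1	0	0	1	1
F046	F046_c1	F046_p1	0	0	1
F047	F047_p1	0	0	2	0
F047	F047_h1	0	F047_p1	0	1
F047	F047_h2	0	F047_p1	0	1
F048	F048_p1	0	0	1	0
F048	F048_p2	0	0	2	0
F048	F048_s1	F048_p1	F048_p2	0	1
F048	F048_s2	F048_p1	F048_p2	0	1
F048	F048_s3	F048_p1	F048_p2	0	1
F049	F049_p1	0	0	1	0
F049	F049_p2	0	0	2	0
F049	F049_s1	F049_p1	F049_p2	0	1
F049	F049_s2	F049_p1	F049_p2	0	1
F049	F049_s3	F049_p1	F049_p2	0	1
F050	F050_p1	0	0	1	1
F050	F050_sp	0	0	2	0
F050	F050_c1	F050_p1	F050_sp	0	1
F050	F050_c2	F050_p1	F050_sp	0	1
F051	F051_p1	0	0	1	1
F051	F051_sp	0	0	2	0
F051	F051_c1	F051_p1	F051_sp	0	1
F051	F051_c2	F051_p1	F051_sp	0	1
F052	F052_g1	0	0	1	0
F052	F052_g2	0	0	2	0
F052	F052_s1	F052_g1	F052_g2	1	1
F052	F052_s2	F052_g1	F052_g2	0	1
F052	F052_c1	F052_s1	0	0	1
F053	F053_g1	0	0	1	0
F053	F053_g2	0	0	2	0
F053	F053_s1	F053_g1	F053_g2	1	1
F053	F053_s2	F053_g1	F053_g2	0	1
F053	F053_c1	F053_s1	0	0	1
F054	F054_g1	0	0	1	0
F054	F054_g2	0	0	2	0
F054	F054_s1	F054_g1	F054_g2	1	1
F054	F054_s2	F054_g1	F054_g2	0	1
F054	F054_c1	F054_s1	0	0	1
F055	F055_g1	0	0	1	0
F055	F055_g2	0	0	2	0
F055	F055_s1	F055_g1	F055_g2	1	1
F055	F055_s2	F055_g1	F055_g2	0	1
F055	F055_c1	F055_s1	0	0	1
F056	F056_g1	0	0	1	0
F056	F056_g2	0	0	2	0
F056	F056_s1	F056_g1	F056_g2	1	1
F056	F056_s2	F056_g1	F056_g2	0	1
F056	F056_c1	F056_s1	0	0	1
F057	F057_g1	0	0	1	0
F057	F057_g2	0	0	2	0
F057	F057_s1	F057_g1	F057_g2	1	1
F057	F057_s2	F057_g1	F057_g2	0	1
F057	F057_c1	F057_s1	0	0	1
F058	F058_g1	0	0	1	0
F058	F058_g2	0	0	2	0
F058	F058_s1	F058_g1	F058_g2	1	1
F058	F058_s2	F058_g1	F058_g2	0	1
F058	F058_c1	F058_s1	0	0	1
F059	F059_g1	0	0	1	0
F059	F059_g2	0	0	2	0
F059	F059_s1	F059_g1	F059_g2	1	1
F059	F059_s2	F059_g1	F059_g2	0	1
F059	F059_c1	F059_s1	0	0	1
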