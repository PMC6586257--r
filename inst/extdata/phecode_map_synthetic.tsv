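icd_version	icd_code	phecode	exclusion_root	description	category	sex
10	D509	280.1	280	Iron deficiency anemias, unspecified or not due to blood loss	Hematopoietic	both
10	D508	280.1	280	Iron deficiency anemias, unspecified or not due to blood loss	Hematopoietic	both
9	2809	280.1	280	Iron deficiency anemias, unspecified or not due to blood loss	Hematopoietic	both
10	D510	281	280	Other deficiency anemia	Hematopoietic	both
10	D528	281	280	Other deficiency anemia	Hematopoietic	both
10	D609	284	280	Aplastic anemia	Hematopoietic	both
10	D619	284	280	Aplastic anemia	Hematopoietic	both
10	D649	285	280	Other anemias	Hematopoietic	both
10	D62	285.1	280	Acute posthemorrhagic anemia	Hematopoietic	both
10	E780	272.11	272	Hypercholesterolemia	Endocrine/metabolic	both
9	2720	272.11	272	Hypercholesterolemia	Endocrine/metabolic	both
10	L0311	681.5	681	Cellulitis and abscess of leg, except foot	Dermatologic	both
10	L0313	681.3	681	Cellulitis and abscess of arm/hand	Dermatologic	both
10	L0303	681.6	681	Cellulitis and abscess of foot, toe	Dermatologic	both
10	L0890	686	686	Other local infections of skin and subcutaneous tissue	Dermatologic	both
10	L989	689	689	Disorder of skin and subcutaneous tissue NOS	Dermatologic	both
10	K140	529.1	529	Glossitis	Digestive	both
10	T360	960	960	Poisoning by antibiotics	Injuries and poisonings	both
10	K8245	575.6	575	Cholesterolosis of gallbladder	Digestive	both
10	I10	401.1	401	Essential hypertension	Circulatory system	both
9	4019	401.1	401	Essential hypertension	Circulatory system	both
10	E119	250.2	250	Type 2 diabetes	Endocrine/metabolic	both
10	J459	495	495	Asthma	Respiratory	both
10	M199	715	715	Osteoarthrosis NOS	Musculoskeletal	both
10	K219	530.11	530	GERD	Digestive	both
10	O039	634	634	Miscarriage	Pregnancy complications	female
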