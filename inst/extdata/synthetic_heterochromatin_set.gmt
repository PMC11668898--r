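SYNTHETIC_HETEROCHROMATIN_FORMATION	synthetic stand-in gene set (91 members) for a heterochromatin-formation pathway; not real GO membership	SYNHET001	SYNHET002	SYNHET003	SYNHET004	SYNHET005	SYNHET006	SYNHET007	SYNHET008	SYNHET009	SYNHET010	SYNHET011	SYNHET012	SYNHET013	SYNHET014	SYNHET015	SYNHET016	SYNHET017	SYNHET018	SYNHET019	SYNHET020	SYNHET021	SYNHET022	SYNHET023	SYNHET024	SYNHET025	SYNHET026	SYNHET027	SYNHET028	SYNHET029	SYNHET030	SYNHET031	SYNHET032	SYNHET033	SYNHET034	SYNHET035	SYNHET036	SYNHET037	SYNHET038	SYNHET039	SYNHET040	SYNHET041	SYNHET042	SYNHET043	SYNHET044	SYNHET045	SYNHET046	SYNHET047	SYNHET048	SYNHET049	SYNHET050	SYNHET051	SYNHET052	SYNHET053	SYNHET054	SYNHET055	SYNHET056	SYNHET057	SYNHET058	SYNHET059	SYNHET060	SYNHET061	SYNHET062	SYNHET063	SYNHET064	SYNHET065	SYNHET066	SYNHET067	SYNHET068	SYNHET069	SYNHET070	SYNHET071	SYNHET072	SYNHET073	SYNHET074	SYNHET075	SYNHET076	SYNHET077	SYNHET078	SYNHET079	SYNHET080	SYNHET081	SYNHET082	SYNHET083	SYNHET084	SYNHET085	SYNHET086	SYNHET087	SYNHET088	SYNHET089	SYNHET090	SYNHET091
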