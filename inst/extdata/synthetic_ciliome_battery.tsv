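gene_id	public_name	category
cil-core-001	cil-core-001	Core components
cil-core-002	cil-core-002	Core components
cil-core-003	cil-core-003	Core components
cil-core-004	cil-core-004	Core components
cil-core-005	cil-core-005	Core components
cil-core-006	cil-core-006	Core components
cil-core-007	cil-core-007	Core components
cil-core-008	cil-core-008	Core components
cil-core-009	cil-core-009	Core components
cil-core-010	cil-core-010	Core components
cil-core-011	cil-core-011	Core components
cil-core-012	cil-core-012	Core components
cil-core-013	cil-core-013	Core components
cil-core-014	cil-core-014	Core components
cil-core-015	cil-core-015	Core components
cil-core-016	cil-core-016	Core components
cil-core-017	cil-core-017	Core components
cil-core-018	cil-core-018	Core components
cil-core-019	cil-core-019	Core components
cil-core-020	cil-core-020	Core components
cil-core-021	cil-core-021	Core components
cil-core-022	cil-core-022	Core components
cil-core-023	cil-core-023	Core components
cil-core-024	cil-core-024	Core components
cil-core-025	cil-core-025	Core components
cil-core-026	cil-core-026	Core components
cil-core-027	cil-core-027	Core components
cil-core-028	cil-core-028	Core components
cil-core-029	cil-core-029	Core components
cil-core-030	cil-core-030	Core components
cil-core-031	cil-core-031	Core components
cil-core-032	cil-core-032	Core components
cil-core-033	cil-core-033	Core components
cil-core-034	cil-core-034	Core components
cil-core-035	cil-core-035	Core components
cil-core-036	cil-core-036	Core components
cil-core-037	cil-core-037	Core components
cil-core-038	cil-core-038	Core components
cil-core-039	cil-core-039	Core components
cil-core-040	cil-core-040	Core components
cil-core-041	cil-core-041	Core components
cil-core-042	cil-core-042	Core components
cil-core-043	cil-core-043	Core components
cil-core-044	cil-core-044	Core components
cil-core-045	cil-core-045	Core components
cil-core-046	cil-core-046	Core components
cil-core-047	cil-core-047	Core components
cil-core-048	cil-core-048	Core components
cil-core-049	cil-core-049	Core components
cil-core-050	cil-core-050	Core components
cil-core-051	cil-core-051	Core components
cil-core-052	cil-core-052	Core components
cil-core-053	cil-core-053	Core components
cil-core-054	cil-core-054	Core components
cil-core-055	cil-core-055	Core components
cil-core-056	cil-core-056	Core components
cil-core-057	cil-core-057	Core components
cil-core-058	cil-core-058	Core components
cil-core-059	cil-core-059	Core components
cil-core-060	cil-core-060	Core components
cil-core-061	cil-core-061	Core components
cil-core-062	cil-core-062	Core components
cil-core-063	cil-core-063	Core components
cil-core-064	cil-core-064	Core components
cil-core-065	cil-core-065	Core components
cil-core-066	cil-core-066	Core components
cil-core-067	cil-core-067	Core components
cil-core-068	cil-core-068	Core components
cil-core-069	cil-core-069	Core components
cil-core-070	cil-core-070	Core components
cil-core-071	cil-core-071	Core components
cil-core-072	cil-core-072	Core components
cil-core-073	cil-core-073	Core components
cil-subtype-001	cil-subtype-001	Subtype specific
cil-subtype-002	cil-subtype-002	Subtype specific
cil-subtype-003	cil-subtype-003	Subtype specific
cil-subtype-004	cil-subtype-004	Subtype specific
cil-subtype-005	cil-subtype-005	Subtype specific
cil-subtype-006	cil-subtype-006	Subtype specific
cil-subtype-007	cil-subtype-007	Subtype specific
cil-subtype-008	cil-subtype-008	Subtype specific
cil-subtype-009	cil-subtype-009	Subtype specific
cil-subtype-010	cil-subtype-010	Subtype specific
cil-subtype-011	cil-subtype-011	Subtype specific
cil-subtype-012	cil-subtype-012	Subtype specific
cil-subtype-013	cil-subtype-013	Subtype specific
cil-subtype-014	cil-subtype-014	Subtype specific
cil-subtype-015	cil-subtype-015	Subtype specific
cil-subtype-016	cil-subtype-016	Subtype specific
cil-subtype-017	cil-subtype-017	Subtype specific
cil-subtype-018	cil-subtype-018	Subtype specific
cil-subtype-019	cil-subtype-019	Subtype specific
cil-subtype-020	cil-subtype-020	Subtype specific
cil-subtype-021	cil-subtype-021	Subtype specific
cil-subtype-022	cil-subtype-022	Subtype specific
cil-subtype-023	cil-subtype-023	Subtype specific
cil-subtype-024	cil-subtype-024	Subtype specific
cil-subtype-025	cil-subtype-025	Subtype specific
cil-subtype-026	cil-subtype-026	Subtype specific
cil-subtype-027	cil-subtype-027	Subtype specific
cil-subtype-028	cil-subtype-028	Subtype specific
cil-subtype-029	cil-subtype-029	Subtype specific
cil-subtype-030	cil-subtype-030	Subtype specific
cil-subtype-031	cil-subtype-031	Subtype specific
cil-subtype-032	cil-subtype-032	Subtype specific
cil-subtype-033	cil-subtype-033	Subtype specific
cil-subtype-034	cil-subtype-034	Subtype specific
cil-subtype-035	cil-subtype-035	Subtype specific
cil-subtype-036	cil-subtype-036	Subtype specific
cil-subtype-037	cil-subtype-037	Subtype specific
cil-subtype-038	cil-subtype-038	Subtype specific
cil-subtype-039	cil-subtype-039	Subtype specific
cil-subtype-040	cil-subtype-040	Subtype specific
cil-subtype-041	cil-subtype-041	Subtype specific
cil-subtype-042	cil-subtype-042	Subtype specific
cil-subtype-043	cil-subtype-043	Subtype specific
cil-subtype-044	cil-subtype-044	Subtype specific
cil-subtype-045	cil-subtype-045	Subtype specific
cil-subtype-046	cil-subtype-046	Subtype specific
cil-subtype-047	cil-subtype-047	Subtype specific
cil-subtype-048	cil-subtype-048	Subtype specific
cil-subtype-049	cil-subtype-049	Subtype specific
cil-subtype-050	cil-subtype-050	Subtype specific
cil-subtype-051	cil-subtype-051	Subtype specific
cil-subtype-052	cil-subtype-052	Subtype specific
cil-subtype-053	cil-subtype-053	Subtype specific
cil-subtype-054	cil-subtype-054	Subtype specific
cil-subtype-055	cil-subtype-055	Subtype specific
cil-subtype-056	cil-subtype-056	Subtype specific
cil-subtype-057	cil-subtype-057	Subtype specific
cil-subtype-058	cil-subtype-058	Subtype specific
cil-subtype-059	cil-subtype-059	Subtype specific
cil-subtype-060	cil-subtype-060	Subtype specific
cil-subtype-061	cil-subtype-061	Subtype specific
cil-subtype-062	cil-subtype-062	Subtype specific
cil-subtype-063	cil-subtype-063	Subtype specific
cil-subtype-064	cil-subtype-064	Subtype specific
cil-subtype-065	cil-subtype-065	Subtype specific
cil-subtype-066	cil-subtype-066	Subtype specific
cil-subtype-067	cil-subtype-067	Subtype specific
cil-subtype-068	cil-subtype-068	Subtype specific
cil-broad-001	cil-broad-001	Broad expression
cil-broad-002	cil-broad-002	Broad expression
cil-broad-003	cil-broad-003	Broad expression
cil-broad-004	cil-broad-004	Broad expression
cil-broad-005	cil-broad-005	Broad expression
cil-broad-006	cil-broad-006	Broad expression
cil-broad-007	cil-broad-007	Broad expression
cil-broad-008	cil-broad-008	Broad expression
cil-broad-009	cil-broad-009	Broad expression
cil-broad-010	cil-broad-010	Broad expression
cil-broad-011	cil-broad-011	Broad expression
cil-broad-012	cil-broad-012	Broad expression
cil-broad-013	cil-broad-013	Broad expression
cil-male-001	cil-male-001	Male
cil-male-002	cil-male-002	Male
cil-male-003	cil-male-003	Male
cil-male-004	cil-male-004	Male
cil-male-005	cil-male-005	Male
cil-male-006	cil-male-006	Male
cil-male-007	cil-male-007	Male
cil-male-008	cil-male-008	Male
cil-male-009	cil-male-009	Male
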