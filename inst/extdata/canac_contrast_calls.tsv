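gene_id	tissue	treatment	timepoint_h	call	ambiguous
CaNAC02	leaf	control	2	lower	FALSE
CaNAC04	leaf	control	2	similar	FALSE
CaNAC05	leaf	control	2	similar	FALSE
CaNAC06	leaf	control	2	lower	FALSE
CaNAC16	leaf	control	2	higher	FALSE
CaNAC19	leaf	control	2	similar	FALSE
CaNAC21	leaf	control	2	similar	FALSE
CaNAC24	leaf	control	2	similar	FALSE
CaNAC27	leaf	control	2	lower	FALSE
CaNAC40	leaf	control	2	lower	FALSE
CaNAC41	leaf	control	2	similar	FALSE
CaNAC43	leaf	control	2	lower	FALSE
CaNAC44	leaf	control	2	similar	FALSE
CaNAC46	leaf	control	2	lower	FALSE
CaNAC47	leaf	control	2	lower	FALSE
CaNAC50	leaf	control	2	lower	FALSE
CaNAC52	leaf	control	2	similar	FALSE
CaNAC57	leaf	control	2	similar	FALSE
CaNAC67	leaf	control	2	lower	FALSE
CaNAC02	leaf	control	5	lower	FALSE
CaNAC04	leaf	control	5	higher	FALSE
CaNAC05	leaf	control	5	similar	FALSE
CaNAC06	leaf	control	5	lower	FALSE
CaNAC16	leaf	control	5	higher	FALSE
CaNAC19	leaf	control	5	lower	FALSE
CaNAC21	leaf	control	5	similar	FALSE
CaNAC24	leaf	control	5	similar	FALSE
CaNAC27	leaf	control	5	lower	FALSE
CaNAC40	leaf	control	5	lower	FALSE
CaNAC41	leaf	control	5	lower	FALSE
CaNAC43	leaf	control	5	lower	FALSE
CaNAC44	leaf	control	5	lower	FALSE
CaNAC46	leaf	control	5	similar	FALSE
CaNAC47	leaf	control	5	similar	FALSE
CaNAC50	leaf	control	5	lower	FALSE
CaNAC52	leaf	control	5	similar	FALSE
CaNAC57	leaf	control	5	similar	FALSE
CaNAC67	leaf	control	5	similar	FALSE
CaNAC02	leaf	stress	2	lower	FALSE
CaNAC04	leaf	stress	2	higher	FALSE
CaNAC05	leaf	stress	2	higher	FALSE
CaNAC06	leaf	stress	2	unknown	FALSE
CaNAC16	leaf	stress	2	higher	FALSE
CaNAC19	leaf	stress	2	unknown	FALSE
CaNAC21	leaf	stress	2	unknown	FALSE
CaNAC24	leaf	stress	2	unknown	FALSE
CaNAC27	leaf	stress	2	unknown	FALSE
CaNAC40	leaf	stress	2	unknown	FALSE
CaNAC41	leaf	stress	2	unknown	FALSE
CaNAC43	leaf	stress	2	unknown	FALSE
CaNAC44	leaf	stress	2	unknown	FALSE
CaNAC46	leaf	stress	2	unknown	FALSE
CaNAC47	leaf	stress	2	unknown	FALSE
CaNAC50	leaf	stress	2	unknown	FALSE
CaNAC52	leaf	stress	2	unknown	FALSE
CaNAC57	leaf	stress	2	unknown	FALSE
CaNAC67	leaf	stress	2	unknown	FALSE
CaNAC02	leaf	stress	5	lower	FALSE
CaNAC04	leaf	stress	5	higher	FALSE
CaNAC05	leaf	stress	5	unknown	FALSE
CaNAC06	leaf	stress	5	unknown	FALSE
CaNAC16	leaf	stress	5	higher	FALSE
CaNAC19	leaf	stress	5	unknown	FALSE
CaNAC21	leaf	stress	5	unknown	FALSE
CaNAC24	leaf	stress	5	unknown	FALSE
CaNAC27	leaf	stress	5	unknown	FALSE
CaNAC40	leaf	stress	5	unknown	FALSE
CaNAC41	leaf	stress	5	unknown	FALSE
CaNAC43	leaf	stress	5	unknown	FALSE
CaNAC44	leaf	stress	5	unknown	FALSE
CaNAC46	leaf	stress	5	unknown	FALSE
CaNAC47	leaf	stress	5	unknown	FALSE
CaNAC50	leaf	stress	5	unknown	FALSE
CaNAC52	leaf	stress	5	unknown	FALSE
CaNAC57	leaf	stress	5	unknown	FALSE
CaNAC67	leaf	stress	5	unknown	FALSE
CaNAC02	root	control	2	lower	FALSE
CaNAC04	root	control	2	similar	FALSE
CaNAC05	root	control	2	similar	FALSE
CaNAC06	root	control	2	lower	FALSE
CaNAC16	root	control	2	higher	FALSE
CaNAC19	root	control	2	similar	FALSE
CaNAC21	root	control	2	similar	FALSE
CaNAC24	root	control	2	higher	FALSE
CaNAC27	root	control	2	lower	FALSE
CaNAC40	root	control	2	lower	FALSE
CaNAC41	root	control	2	similar	FALSE
CaNAC43	root	control	2	lower	FALSE
CaNAC44	root	control	2	similar	FALSE
CaNAC46	root	control	2	similar	FALSE
CaNAC47	root	control	2	lower	FALSE
CaNAC50	root	control	2	lower	FALSE
CaNAC52	root	control	2	similar	FALSE
CaNAC57	root	control	2	similar	FALSE
CaNAC67	root	control	2	similar	FALSE
CaNAC02	root	control	5	lower	FALSE
CaNAC04	root	control	5	higher	FALSE
CaNAC05	root	control	5	similar	FALSE
CaNAC06	root	control	5	lower	FALSE
CaNAC16	root	control	5	higher	FALSE
CaNAC19	root	control	5	similar	FALSE
CaNAC21	root	control	5	similar	FALSE
CaNAC24	root	control	5	similar	FALSE
CaNAC27	root	control	5	lower	FALSE
CaNAC40	root	control	5	lower	FALSE
CaNAC41	root	control	5	similar	FALSE
CaNAC43	root	control	5	lower	FALSE
CaNAC44	root	control	5	similar	FALSE
CaNAC46	root	control	5	similar	FALSE
CaNAC47	root	control	5	lower	FALSE
CaNAC50	root	control	5	lower	FALSE
CaNAC52	root	control	5	similar	FALSE
CaNAC57	root	control	5	similar	FALSE
CaNAC67	root	control	5	similar	FALSE
CaNAC02	root	stress	2	lower	TRUE
CaNAC04	root	stress	2	higher	TRUE
CaNAC05	root	stress	2	similar	TRUE
CaNAC06	root	stress	2	lower	TRUE
CaNAC16	root	stress	2	higher	TRUE
CaNAC19	root	stress	2	similar	TRUE
CaNAC21	root	stress	2	similar	TRUE
CaNAC24	root	stress	2	higher	TRUE
CaNAC27	root	stress	2	lower	TRUE
CaNAC40	root	stress	2	similar	TRUE
CaNAC41	root	stress	2	similar	TRUE
CaNAC43	root	stress	2	lower	TRUE
CaNAC44	root	stress	2	similar	TRUE
CaNAC46	root	stress	2	similar	TRUE
CaNAC47	root	stress	2	similar	TRUE
CaNAC50	root	stress	2	lower	TRUE
CaNAC52	root	stress	2	similar	TRUE
CaNAC57	root	stress	2	similar	TRUE
CaNAC67	root	stress	2	similar	TRUE
CaNAC02	root	stress	5	lower	FALSE
CaNAC04	root	stress	5	higher	FALSE
CaNAC05	root	stress	5	similar	FALSE
CaNAC06	root	stress	5	lower	FALSE
CaNAC16	root	stress	5	higher	FALSE
CaNAC19	root	stress	5	similar	FALSE
CaNAC21	root	stress	5	similar	FALSE
CaNAC24	root	stress	5	higher	FALSE
CaNAC27	root	stress	5	higher	FALSE
CaNAC40	root	stress	5	similar	FALSE
CaNAC41	root	stress	5	similar	FALSE
CaNAC43	root	stress	5	similar	FALSE
CaNAC44	root	stress	5	similar	FALSE
CaNAC46	root	stress	5	similar	FALSE
CaNAC47	root	stress	5	similar	FALSE
CaNAC50	root	stress	5	lower	FALSE
CaNAC52	root	stress	5	similar	FALSE
CaNAC57	root	stress	5	similar	FALSE
CaNAC67	root	stress	5	similar	FALSE
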