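gene_id	cultivar	tissue	pattern
CaNAC02	Hashem	leaf	down
CaNAC04	Hashem	leaf	down
CaNAC05	Hashem	leaf	up
CaNAC06	Hashem	leaf	up
CaNAC16	Hashem	leaf	up
CaNAC19	Hashem	leaf	up
CaNAC21	Hashem	leaf	up
CaNAC24	Hashem	leaf	down
CaNAC27	Hashem	leaf	up
CaNAC40	Hashem	leaf	up
CaNAC41	Hashem	leaf	up
CaNAC43	Hashem	leaf	up
CaNAC44	Hashem	leaf	unchanged
CaNAC46	Hashem	leaf	down
CaNAC47	Hashem	leaf	up
CaNAC50	Hashem	leaf	up
CaNAC52	Hashem	leaf	up
CaNAC57	Hashem	leaf	up
CaNAC67	Hashem	leaf	up
CaNAC02	ILC482	leaf	down
CaNAC04	ILC482	leaf	down
CaNAC05	ILC482	leaf	up
CaNAC06	ILC482	leaf	up
CaNAC16	ILC482	leaf	up
CaNAC19	ILC482	leaf	up
CaNAC21	ILC482	leaf	up
CaNAC24	ILC482	leaf	mixed
CaNAC27	ILC482	leaf	up
CaNAC40	ILC482	leaf	up
CaNAC41	ILC482	leaf	up
CaNAC43	ILC482	leaf	up
CaNAC44	ILC482	leaf	up
CaNAC46	ILC482	leaf	up
CaNAC47	ILC482	leaf	up
CaNAC50	ILC482	leaf	up
CaNAC52	ILC482	leaf	up
CaNAC57	ILC482	leaf	up
CaNAC67	ILC482	leaf	up
CaNAC02	Hashem	root	down
CaNAC04	Hashem	root	down
CaNAC05	Hashem	root	unchanged
CaNAC06	Hashem	root	up
CaNAC16	Hashem	root	up
CaNAC19	Hashem	root	up
CaNAC21	Hashem	root	unchanged
CaNAC24	Hashem	root	up
CaNAC27	Hashem	root	up
CaNAC40	Hashem	root	up
CaNAC41	Hashem	root	unchanged
CaNAC43	Hashem	root	up
CaNAC44	Hashem	root	up
CaNAC46	Hashem	root	down
CaNAC47	Hashem	root	unchanged
CaNAC50	Hashem	root	up
CaNAC52	Hashem	root	up
CaNAC57	Hashem	root	unchanged
CaNAC67	Hashem	root	up
CaNAC02	ILC482	root	down
CaNAC04	ILC482	root	unchanged
CaNAC05	ILC482	root	unchanged
CaNAC06	ILC482	root	up
CaNAC16	ILC482	root	up
CaNAC19	ILC482	root	up
CaNAC21	ILC482	root	unchanged
CaNAC24	ILC482	root	up
CaNAC27	ILC482	root	up
CaNAC40	ILC482	root	up
CaNAC41	ILC482	root	unchanged
CaNAC43	ILC482	root	up
CaNAC44	ILC482	root	unchanged
CaNAC46	ILC482	root	down
CaNAC47	ILC482	root	up
CaNAC50	ILC482	root	up
CaNAC52	ILC482	root	up
CaNAC57	ILC482	root	unchanged
CaNAC67	ILC482	root	up
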