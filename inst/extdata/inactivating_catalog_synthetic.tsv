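position	ref	alt	source
291	C	G	synthetic
293	C	T	synthetic
296	C	T	synthetic
296	C	A	synthetic
299	C	T	synthetic
302	C	T	synthetic
404	G	A	synthetic
412	G	A	synthetic
416	G	A	synthetic
604	C	T	synthetic
610	C	G	synthetic
943	C	T	synthetic
945	C	T	synthetic
956	C	T	synthetic
958	C	T	synthetic
1110	G	A	synthetic
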