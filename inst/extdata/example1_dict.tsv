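id	type	primary_term	synonyms
SLC6A2	marker	SLC6A2	
SLC6A4	marker	SLC6A4	
G1287A	marker	G1287A	
5-HIT	marker	5-HIT	
OCD	disease	OCD	obsessive-compulsive disorder
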