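In some studies, SLC6A2 and SLC6A4 are linked, whereas susceptibility to OCD was linked to G1287A and 5-HIT
(CU (S (PP In (NP some studies)) , (NP SLC6A2 and SLC6A4) (VP are linked)) , whereas (S (NP susceptibility (PP to (NP OCD))) (VP was linked (PP to (NP G1287A and 5-HIT)))))
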