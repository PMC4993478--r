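<http://example.org/A/C1> <http://example.org/A/p1> <http://example.org/A/C2> .
<http://example.org/A/C2> <http://example.org/A/p3> <http://example.org/B/C4> .
<http://example.org/B/C3> <http://example.org/B/p2> <http://example.org/A/C2> .
<http://example.org/B/C3> <http://example.org/B/p4> <http://example.org/B/C5> .
<http://example.org/B/C4> <http://example.org/B/p5> <http://example.org/B/C6> .
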