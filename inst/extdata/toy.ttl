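@prefix a: <http://example.org/A/> .
@prefix b: <http://example.org/B/> .

# two-domain toy vocabulary
a:C1 a:p1 a:C2 .
b:C3 b:p2 a:C2 ;
     b:p4 b:C5 .
a:C2 a:p3 b:C4 .
b:C4 b:p5 b:C6 .
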