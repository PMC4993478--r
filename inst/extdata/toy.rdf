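<?xml version="1.0" encoding="UTF-8"?>
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:a="http://example.org/A/"
         xmlns:b="http://example.org/B/">
  <rdf:Description rdf:about="http://example.org/A/C1">
    <a:p1 rdf:resource="http://example.org/A/C2"/>
  </rdf:Description>
  <rdf:Description rdf:about="http://example.org/B/C3">
    <b:p2 rdf:resource="http://example.org/A/C2"/>
    <b:p4 rdf:resource="http://example.org/B/C5"/>
  </rdf:Description>
  <rdf:Description rdf:about="http://example.org/A/C2">
    <a:p3 rdf:resource="http://example.org/B/C4"/>
  </rdf:Description>
  <rdf:Description rdf:about="http://example.org/B/C4">
    <b:p5 rdf:resource="http://example.org/B/C6"/>
  </rdf:Description>
</rdf:RDF>
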