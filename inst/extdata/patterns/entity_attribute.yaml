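# Basic entity-attribute trait pattern: an attribute-level characteristic
# borne by a biological entity (chemical or anatomical).
pattern_id: entity_attribute
vars:
  attribute: PATO:0000001
  entity: owl:Thing
name:
  text: "%s %s"
  vars: [entity, attribute]
def:
  text: "The %s of %s."
  vars: [attribute, entity]
synonyms:
  - text: "%s of %s"
    vars: [attribute, entity]
    scope: EXACT
equivalent_to:
  text: "%s and (RO:0000052 some %s)"
  vars: [attribute, entity]
gcis:
  - sub:
      text: "%s and (RO:0000052 some (BFO:0000050 some %s))"
      vars: [attribute, entity]
    sup:
      text: "BFO:0000050 some (%s and (RO:0000052 some %s))"
      vars: [attribute, entity]
roles:
  RO:0000052: characteristic of
  BFO:0000050: part of
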