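# Chemical-in-entity attribute: an amount-like characteristic of a
# chemical located in an anatomical entity ("blood glucose amount").
pattern_id: chemical_in_entity_attribute
vars:
  attribute: PATO:0000001
  chemical: CHEBI:24431
  location: UBERON:0001062
name:
  text: "%s %s %s"
  vars: [location, chemical, attribute]
def:
  text: "The %s of %s in the %s."
  vars: [attribute, chemical, location]
synonyms:
  - text: "%s in %s %s"
    vars: [chemical, location, attribute]
    scope: EXACT
equivalent_to:
  text: "%s and (RO:0000052 some (%s and (BFO:0000050 some %s)))"
  vars: [attribute, chemical, location]
roles:
  RO:0000052: characteristic of
  BFO:0000050: part of
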