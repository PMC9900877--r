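# Phenotypic-abnormality shape: a state-level characteristic of a bearer
# with an abnormal modifier. Used for phenotype fixtures, not for traits.
pattern_id: abnormality
vars:
  attribute: PATO:0000001
  entity: owl:Thing
name:
  text: "abnormal %s %s"
  vars: [entity, attribute]
def:
  text: "An abnormal %s of %s."
  vars: [attribute, entity]
equivalent_to:
  text: "%s and (RO:0000052 some %s) and (RO:0002573 some PATO:0000460)"
  vars: [attribute, entity]
roles:
  RO:0000052: characteristic of
  RO:0002573: has modifier
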