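# Role-based attribute: the characteristic of whatever bears a chemical
# role ("serum metabolite amount").
pattern_id: role_attribute
vars:
  attribute: PATO:0000001
  role: CHEBI:50906
name:
  text: "%s %s"
  vars: [role, attribute]
def:
  text: "The %s of any chemical entity with the %s role."
  vars: [attribute, role]
equivalent_to:
  text: "%s and (RO:0000087 some %s)"
  vars: [attribute, role]
roles:
  RO:0000087: has role
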