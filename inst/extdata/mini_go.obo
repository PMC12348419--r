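format-version: 1.2
data-version: synthetic-mini/2025-01-01
ontology: go

[Term]
id: GO:0003674
name: molecular_function
namespace: molecular_function

[Term]
id: GO:0005215
name: transporter activity
namespace: molecular_function
is_a: GO:0003674 ! molecular_function

[Term]
id: GO:0022857
name: transmembrane transporter activity
namespace: molecular_function
is_a: GO:0005215 ! transporter activity

[Term]
id: GO:0015171
name: amino acid transmembrane transporter activity
namespace: molecular_function
is_a: GO:0022857 ! transmembrane transporter activity

[Term]
id: GO:0051119
name: sugar transmembrane transporter activity
namespace: molecular_function
is_a: GO:0022857 ! transmembrane transporter activity

[Term]
id: GO:0015173
name: aromatic amino acid transmembrane transporter activity
namespace: molecular_function
is_a: GO:0015171 ! amino acid transmembrane transporter activity

[Term]
id: GO:0005351
name: carbohydrate:proton symporter activity
namespace: molecular_function
is_a: GO:0051119 ! sugar transmembrane transporter activity
is_a: GO:0015293 ! symporter activity

[Term]
id: GO:0015293
name: symporter activity
namespace: molecular_function
is_a: GO:0022857 ! transmembrane transporter activity

[Term]
id: GO:0022836
name: gated channel activity
namespace: molecular_function
is_a: GO:0022857 ! transmembrane transporter activity

[Term]
id: GO:0004970
name: glutamate-gated receptor ion channel activity
namespace: molecular_function
is_a: GO:0022836 ! gated channel activity
is_a: GO:0015171 ! amino acid transmembrane transporter activity

[Term]
id: GO:0016020
name: membrane
namespace: cellular_component

[Term]
id: GO:0099999
name: obsolete sugar porter activity
namespace: molecular_function
is_obsolete: true

[Term]
id: GO:0008643
name: carbohydrate transport regulator
namespace: molecular_function
relationship: part_of GO:0051119 ! sugar transmembrane transporter activity
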