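format-version: 1.2

[Term]
id: neoplasms-by-histologic-type
name: Neoplasms by Histologic Type

[Term]
id: leukemia
name: Leukemia
is_a: neoplasms-by-histologic-type

[Term]
id: leukemia-lymphoid
name: Leukemia, Lymphoid
synonym: "Lymphoid Leukemia" EXACT []
is_a: leukemia

[Term]
id: leukemia-b-cell
name: Leukemia, B-Cell
synonym: "B-Cell Leukemia" EXACT []
is_a: leukemia-lymphoid

[Term]
id: leukemia-t-cell
name: Leukemia, T-Cell
synonym: "T-Cell Leukemia" EXACT []
is_a: leukemia-lymphoid

[Term]
id: leukemia-large-granular-lymphocytic
name: Leukemia, Large Granular Lymphocytic
is_a: leukemia-t-cell

[Term]
id: leukemia-prolymphocytic-t-cell
name: Leukemia, Prolymphocytic, T-Cell
is_a: leukemia-t-cell

[Term]
id: leukemia-lymphoma-adult-t-cell
name: Leukemia-Lymphoma, Adult T-Cell
is_a: leukemia-t-cell

[Term]
id: diabetes-mellitus
name: Diabetes Mellitus

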