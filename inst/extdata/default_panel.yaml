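name: prostate19
n_markers: 19
n_assays: 24
markers:
- marker_id: ADCY4
  gene: ADCY4
  assays:
  - assay_id: ADCY4
    strand_variant: forward
    bisulfite_group: 42min80C
- marker_id: AOX1
  gene: AOX1
  assays:
  - assay_id: AOX1rc
    strand_variant: reverse-complement
    bisulfite_group: 14min70C
- marker_id: APC2
  gene: APC
  assays:
  - assay_id: APC2
    strand_variant: forward
    bisulfite_group: 42min80C
    aliases: APC
- marker_id: CXCL14
  gene: CXCL14
  assays:
  - assay_id: CXCL14
    strand_variant: forward
    bisulfite_group: 42min80C
  - assay_id: CXCL14rc
    strand_variant: reverse-complement
    bisulfite_group: 42min80C
- marker_id: EPHX3
  gene: EPHX3
  assays:
  - assay_id: EPHX3
    strand_variant: forward
    bisulfite_group: 14min70C
- marker_id: GFRA2
  gene: GFRA2
  assays:
  - assay_id: GFRA2
    strand_variant: forward
    bisulfite_group: 42min80C
- marker_id: GSTP1
  gene: GSTP1
  assays:
  - assay_id: GSTP1
    strand_variant: forward
    bisulfite_group: 42min80C
- marker_id: HEMK1
  gene: HEMK1
  assays:
  - assay_id: HEMK1
    strand_variant: forward
    bisulfite_group: 42min80C
    aliases: HEMK1rc
- marker_id: HOXA7
  gene: HOXA7
  assays:
  - assay_id: HOXA7
    strand_variant: forward
    bisulfite_group: 14min70C
- marker_id: HOXB5
  gene: HOXB5
  assays:
  - assay_id: HOXB5
    strand_variant: forward
    bisulfite_group: 42min80C
  - assay_id: HOXB5rc
    strand_variant: reverse-complement
    bisulfite_group: 42min80C
- marker_id: HOXD10
  gene: HOXD10
  assays:
  - assay_id: HOXD10
    strand_variant: forward
    bisulfite_group: 14min70C
- marker_id: HOXD3a
  gene: HOXD3
  assays:
  - assay_id: HOXD3a
    strand_variant: forward
    bisulfite_group: 14min70C
- marker_id: HOXD3b
  gene: HOXD3
  assays:
  - assay_id: HOXD3b
    strand_variant: forward
    bisulfite_group: 14min70C
- marker_id: HOXD9
  gene: HOXD9
  assays:
  - assay_id: HOXD9
    strand_variant: forward
    bisulfite_group: 42min80C
- marker_id: KIFC2
  gene: KIFC2
  assays:
  - assay_id: KIFC2
    strand_variant: forward
    bisulfite_group: 42min80C
  - assay_id: KIFC2rc
    strand_variant: reverse-complement
    bisulfite_group: 42min80C
- marker_id: MOXD1
  gene: MOXD1
  assays:
  - assay_id: MOXD1
    strand_variant: forward
    bisulfite_group: 42min80C
- marker_id: NEUROG3
  gene: NEUROG3
  assays:
  - assay_id: NEUROG3
    strand_variant: forward
    bisulfite_group: 42min80C
- marker_id: NODAL
  gene: NODAL
  assays:
  - assay_id: NODAL
    strand_variant: forward
    bisulfite_group: 14min70C
  - assay_id: NODALrc
    strand_variant: reverse-complement
    bisulfite_group: 14min70C
- marker_id: RASSF5
  gene: RASSF5
  assays:
  - assay_id: RASSF5
    strand_variant: forward
    bisulfite_group: 42min80C
  - assay_id: RASSF5rc
    strand_variant: reverse-complement
    bisulfite_group: 42min80C
control_assays:
- assay_id: NSD1
  bisulfite_group: 14min70C
- assay_id: HOXD9ctrl
  bisulfite_group: 42min80C
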