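# Reference sequence drop-ins

The alignment- and mass-reproduction checks compare against the real
database sequences, which are not bundled with the package. To enable
them, fetch the proteins from GenBank and place two FASTA files here
(or in `inst/extdata/` of a source checkout) before installing:

- `cglutamicum_references.fasta` — the five *C. glutamicum* ATCC 13032
  IMPase-like proteins, with record ids `HisN` (cg0910), `Cg0911`
  (cg0911), `ImpA` (cg2298), `SuhB` (cg2090), `CysQ` (cg0967), from
  genome accessions BX927147.1 / BA000036.3.
- `orthologs.fasta` — validated HolPase orthologs, at minimum `HisN_Zm`
  (*Zymomonas mobilis* ZM4 locus ZMO_RS06805).

All other functionality, including the classifier and the test-suite
fixtures, uses synthetic reference scaffolds generated in code
(`make_family_reference()`), which satisfy the shipped motif rules but
share nothing else with the database sequences.
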