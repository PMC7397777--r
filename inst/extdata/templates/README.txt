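SYNTHETIC anchor-template library (stand-in data, generated, not derived
from any experimental structure).

alleles.tsv          allele -> supertype assignments used by the lookup
                     fallback chain (exact allele -> supertype -> default)
anchors_<id>.tsv     N- and C-terminal anchor backbone coordinates (N, CA,
                     C rows; x, y, z in Angstrom) in a canonical groove
                     frame whose x axis runs from the A pocket to the F
                     pocket.  Files exist per supertype plus a global
                     "default".

Real template libraries would be built from crystal structures of
peptide-HLA complexes; the shipped files are synthetic placeholders with
the canonical ~23.5 A anchor spacing of a bound 9-mer.
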