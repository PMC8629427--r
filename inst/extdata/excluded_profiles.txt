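# Default profile exclusion list (accessions or name globs, one per line).
# Five classes of domain profiles are excluded from codon decoding because
# their emission structure misleads it: mitochondrial proteins, viral
# proteins, selenoproteins, pyrrolysine-containing proteins, and
# transposon/mobile-element proteins. The exact accession membership of
# these classes is database-release-specific; this file is a best-effort,
# user-editable stand-in matched against both profile accession and name.
# Edit or replace it to suit the profile database in use.

# mobile genetic elements / transposons
Transposase*
Integrase*
DDE_Tnp*
rve*
Phage_integrase*
Tn3*
IstB*

# viral proteins
Phage_*
Viral_*
Gag_*
RVT_*
Capsid*

# mitochondrial proteins (nuclear-encoded organellar families)
Mito_*
NADHdh*
Oxidored_q*

# selenoproteins
SelP*
GSHPx*
Sel1*

# pyrrolysine-containing proteins
MtmB*
MttB*
PylS*
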