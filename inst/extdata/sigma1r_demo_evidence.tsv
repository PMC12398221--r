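# Curated qualitative evidence for the sigma-1 receptor demo triage.
# These are hand-transcribed qualitative assessments (transmembrane
# location, structural burial in the folded receptor, ortholog retention),
# supplied as demo INPUT so the worked example can run without an ortholog
# alignment or structure download. They are not computed by the package.
# start/end refer to the LIR core on the 223-aa human sequence.
start	end	tm_excluded	exposed_monomer	exposed_assembly	retention
11	14	TRUE	FALSE	FALSE	0.20
27	30	TRUE	FALSE	FALSE	0.20
49	52	FALSE	TRUE	TRUE	0.80
58	61	FALSE	TRUE	TRUE	0.70
81	84	FALSE	TRUE	FALSE	1.00
103	106	FALSE	TRUE	TRUE	0.85
121	124	FALSE	FALSE	FALSE	0.90
196	199	FALSE	FALSE	FALSE	0.90
200	203	FALSE	TRUE	TRUE	0.90
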