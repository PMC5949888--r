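# Nine-amino-acid transactivation-domain (9aaTAD) motif patterns.
# SYNTHETIC reconstruction from the published positional residue
# preferences of the motif (four stringency tiers); not a verbatim copy of
# the original web-resource expressions. Replace this file to use the
# original patterns.
[MDENQSTYG][ILVFWMAY][ILVFWMAY][ILVFWMDENQSTYGPA][ILVFWMAY][DENQSTYGPA][ILVFWMAYPG][DENQSTYGPA][DENQSTYGPA]
[MDENQSTYGA][ILVFWMAY][ILVFWMAY][ILVFWMDENQSTYGPA][ILVFWMAYNQ][DENQSTYGPA][ILVFWMAYPGR][DENQSTYGPA][DENQSTYGPAKR]
[MDENQSTYG][ILVFWMAY][ILVFWMAYDE][ILVFWMDENQSTYGPA][ILVFWMAY][DENQSTYGPA].[DENQSTYGPA].
.[ILVFWMAY][ILVFWMAY].[ILVFWMAY][DENQSTYGPA]...
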