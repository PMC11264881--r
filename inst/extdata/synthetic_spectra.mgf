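# Synthetic example spectra (generated by hand for documentation/tests;
# not measured data). Betaine-like precursor m/z with arbitrary fragments.
BEGIN IONS
TITLE=synthetic_query_01
PEPMASS=160.1332
58.0651 100.0
59.0730 35.2
101.1073 5.1
142.1226 12.9
160.1332 8.0
END IONS

BEGIN IONS
TITLE=synthetic_library_01
PEPMASS=160.1338
58.0653 96.5
59.0731 33.0
101.1070 6.2
142.1230 11.1
END IONS
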