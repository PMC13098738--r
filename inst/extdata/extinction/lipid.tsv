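# Absorption coefficient of pure lipid (soybean-oil-style spectrum),
# red/NIR window; small everywhere below the 930 nm CH overtone band.
# Approximate compilation; linear interpolation between rows.
# columns: wavelength_nm  mua_mm1
650	0.00005
675	0.00006
700	0.00007
725	0.00012
750	0.00030
760	0.00040
775	0.00028
800	0.00020
825	0.00024
850	0.00030
875	0.00055
900	0.00110
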