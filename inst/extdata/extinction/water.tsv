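# Absorption coefficient of pure water, red/NIR window.
# Approximate compilation after the standard transmission measurements
# (Hale/Querry-style tabulations); linear interpolation between rows.
# columns: wavelength_nm  mua_mm1
650	0.00032
660	0.00036
670	0.00040
680	0.00043
690	0.00047
700	0.00060
710	0.00080
720	0.00104
730	0.00168
740	0.00266
750	0.00261
760	0.00250
770	0.00235
780	0.00220
790	0.00212
800	0.00206
810	0.00210
820	0.00240
830	0.00291
840	0.00350
850	0.00430
860	0.00460
870	0.00500
880	0.00550
890	0.00610
900	0.00680
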