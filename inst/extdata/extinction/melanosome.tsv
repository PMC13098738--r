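# Absorption coefficient of the melanosome interior (eumelanin-dominated),
# generated from the standard power-law parameterization
# mua[cm^-1] = 1.70e12 * lambda[nm]^-3.48, converted to mm^-1.
# Scaled by the epidermal melanosome volume fraction when building mu_a.
# columns: wavelength_nm  mua_mm1
650	27.63824
660	26.20813
670	24.87188
680	23.62207
690	22.45195
700	21.35540
710	20.32684
720	19.36118
730	18.45378
740	17.60040
750	16.79715
760	16.04049
770	15.32714
780	14.65412
790	14.01866
800	13.41825
810	12.85053
820	12.31336
830	11.80476
840	11.32288
850	10.86603
860	10.43264
870	10.02125
880	9.63051
890	9.25916
900	8.90605
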