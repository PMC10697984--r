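# Material constants for electron collision stopping-power evaluation.
# density in g/cm^3, mean excitation energy I in eV, Z/A dimensionless,
# Sternheimer density-effect coefficients (x0, x1, Cbar, m, delta0); the
# bridge coefficient a is derived from continuity at x0.
name,density_g_cm3,I_eV,Z_over_A,x0,x1,cbar,m,delta0
water_liquid,1.000,75.0,0.55508,0.2400,2.8004,3.5017,3.4773,0
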