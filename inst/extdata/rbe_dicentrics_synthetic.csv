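# SYNTHETIC calibration table: maximum low-dose RBE (RBE_M) for dicentric
# chromosome aberrations in human lymphocytes versus photon energy, relative
# to Co-60 gamma rays. These values are a constructed stand-in emulating the
# published dicentric photon-energy response (RBE_M ~ 1 at the Co-60
# reference, rising toward soft photon energies, with the large relative
# uncertainties typical of cytogenetic data). Replace with real calibration
# data for substantive use.
photon_energy_MeV,rbe_m,std_u
0.0048,3.00,0.90
0.0165,2.40,0.70
0.029,2.10,0.60
0.060,1.70,0.50
0.100,1.45,0.45
0.220,1.25,0.40
0.662,1.05,0.32
1.25,1.00,0.30
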