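# cgnp default force field for SAM-AuNP coarse-grained models.
#
# Units: epsilon kJ/mol, sigma/b0 Angstrom, k_b kJ/mol/A^2,
#        k_theta kJ/mol/rad^2, theta0 degrees.
#
# The CD cross terms are the fitted grid-search values; the Au/CD diagonal
# entries implement the purely repulsive core rules; diagonal entries for
# the shell, water and ion beads are reference values used for solvent
# fixtures and Lorentz-Berthelot guesses (see vignette for caveats).
# Bonded terms are provisional placeholders to be replaced by
# Boltzmann-inverted values from target atomistic distributions.

dielectric 80

bead Au  196.97 0
bead CD   32.06 0
bead CM   42.08 0
bead CM2  28.05 0
bead CT2  29.06 0
bead CT   43.09 0
bead ASP  44.01 -1
bead W    54.05 0
bead SOD  22.99 1
bead CLA  35.45 -1

# fitted core-decoy cross terms
pair CD CM  lj9-6  0.2760 3.798 fitted
pair CD CT2 lj9-6  0.3284 4.078 fitted
pair CD CM2 lj9-6  0.2489 4.176 fitted
pair CD W   lj12-4 0.2517 3.774 fitted
pair CD SOD lj9-6  0.2517 3.774 similarity
pair CD CLA lj9-6  0.2517 3.774 similarity

# purely repulsive core interactions
pair Au Au lj9-6 0.0001 4.0   repulsive
pair CD CD lj9-6 0.0001 2.785 repulsive

# diagonal reference parameters (solvents, water, ions)
pair W   W   lj12-4 3.7447 4.371 reference
pair CM  CM  lj9-6  1.7573 4.506 reference
pair CT  CT  lj9-6  1.9623 4.585 reference
pair CT2 CT2 lj9-6  1.3054 4.221 reference
pair CM2 CM2 lj9-6  1.5062 4.340 reference
pair ASP ASP lj9-6  1.8410 4.114 reference
pair SOD SOD lj9-6  1.4644 4.200 reference
pair CLA CLA lj9-6  1.4644 4.400 reference

# similarity substitution rules for unparameterized CD pairs
similar CD ASP from CD CT2
similar CD SOD from CD W
similar CD CLA from CD W

# provisional bonded terms (grafting bond CD-A, ligand backbone)
bond CD  CM2 10.0 3.30
bond CM2 CM2 25.8 3.00
bond CM2 CT2 25.8 3.05
bond CM2 CM  25.8 3.30
bond CM  CM  25.8 3.64
bond CM  ASP 25.8 3.50

angle CD  CM2 CM2 10.0 165
angle CM2 CM2 CM2  5.0 173
angle CM2 CM2 CT2  5.0 172
angle CM2 CM2 CM   5.0 172
angle CM2 CM  CM   5.0 173
angle CM  CM  ASP  5.0 170
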