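# acidscale

Self-consistent Brønsted acidity scales in low-permittivity solvents.

## The problem

In weakly ion-solvating media such as 1,2-difluorobenzene (1,2-DFB,
relative permittivity ε<sub>r</sub> = 13.4), acids do not dissociate to free
ions — deprotonation yields ion pairs, and the activity of the solvated
proton cannot be measured directly. Absolute pK<sub>a</sub> values are
therefore out of reach of any single titration. What *can* be measured
precisely is the **relative** acidity of two acids sharing one solution:

- UV–vis spectra of a jointly titrated acid pair give the dissociation
  degrees α₁, α₂ of both acids, and with them the ion-pair acidity
  difference ΔpK<sub>ip</sub> = log₁₀[α₁(1−α₂)/(α₂(1−α₁))];
- the Fuoss sphere-in-continuum model corrects for the differing ion-pair
  dissociation of the two salts, ΔpK<sub>a</sub> = ΔpK<sub>ip</sub> +
  ΔpK<sub>d</sub>;
- many overlapping pairwise measurements form a graph ("ladder") whose node
  values are assigned by least squares, minimising
  SS = Σᵢ {Δᵢ − [x(b<sub>i</sub>) − x(a<sub>i</sub>)]}², with the internal
  scatter summarised by the consistency standard deviation
  s = √(SS/(n<sub>m</sub> − n<sub>c</sub>));
- the floating relative scale is anchored — to computed pK<sub>a</sub>
  values of reference acids, or to bridging solutions of known
  aqueous-aligned unified acidity pH<sub>abs</sub><sup>H₂O</sup>;
- differential potentiometry provides an independent route: potential
  differences between two glass electrodes convert to unified-acidity
  differences via ΔpH<sub>abs</sub> = ΔE / slope<sub>mean</sub>.

The package implements this entire pipeline for anyone building or auditing
an acidity scale in such a solvent: spectral unmixing, Fuoss corrections,
the graph least-squares ladder with outlier-series exclusion, potentiometric
trace QC, cross-solvent pK<sub>a</sub> transfer regressions with rule-based
uncertainties, and conversion of solvent-scale pK<sub>a</sub> values to
pH<sub>abs</sub><sup>H₂O</sup> through proton solvation Gibbs energies.
Seeded synthetic-data generators emulate every raw data type, so each stage
is testable end to end without instrument files.

## Worked example

Transfer regression from acetonitrile and a three-acid ladder:

```r
library(acidscale)

t3 <- load_fixture("table3")     # 33 directly measured acids, three solvents
fm <- fit_transfer(t3$pka_mecn, t3$pka_dfb, source = "MeCN", target = "1,2-DFB")
fm
#> pKa(1,2-DFB) = 1.10(0.02) pKa(MeCN) +28.40(0.26)   n = 29, sigma = 0.44, r2 = 0.9892 [all]
predict(fm, 11.00)               # picric acid's MeCN value
#>    x estimate extrapolated
#> 1 11     40.5        FALSE

m <- data.frame(node_a = c("picric", "acid27", "picric"),
                node_b = c("acid27", "acid30", "acid30"),
                delta  = c(-6.05, -1.15, -7.15))
fit <- fit_ladder(m, anchor_set(c(picric = 40.8)))
fit
#> Ladder least-squares fit (fixed_single anchoring)
#>   nodes: 3   measurements: 3 included / 3 total
#>   consistency s: 0.0289  (n_m = 3 , n_c = 2 )
coef(fit)
#>   acid27   acid30   picric
#> 34.76667 33.63333 40.80000

pka_to_phabs_h2o(40.8)           # equimolar picric buffer on the aqueous scale
#> [1] 4.710361
```

The slope above 1 says 1,2-DFB differentiates acid strengths slightly more
than acetonitrile; the consistency s estimates the one-sigma scatter of the
ladder; the last line aligns a solvent-scale pK<sub>a</sub> with the
conventional aqueous pH scale using the proton solvation energies
(−899 kJ/mol in 1,2-DFB, −1105 kJ/mol in water).

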