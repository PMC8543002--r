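# skifuse

Multi-sensor analysis of roller-ski skating sessions on varying treadmill
terrain, for exercise physiologists and biomechanists working with
cross-country skiing data.

A skating session on varying terrain loads the body like interval training:
heart rate (HR), oxygen uptake (V̇O₂) and muscle oxygen saturation (TSI)
swing with every ascent, and the skier continually re-selects gears
(sub-techniques G2/G3/G4), cycle characteristics and the split of
propulsive power between poles and skis. skifuse turns the raw sensor
streams of such a session — chest/wrist/ski inertial units (256 Hz), pole
axial forces (100 Hz), motion-capture markers (200 Hz), HR (1 Hz), 10 s
mixing-chamber V̇O₂ and NIRS oximetry — into a 1 Hz master timeline and the
summary statistics used to compare low- (LI) and high-intensity (HI)
training.

The core quantities:

* **Cycle detection & classification** — cycle starts are minima of the
  Gaussian-smoothed mediolateral chest acceleration ("left-position"); a
  radial-kernel SVM labels each cycle G2/G3/G4/other; cycle length and
  rate satisfy CL·CR/60 = speed.
* **Contact times** — pole contact from the wrist vibration onset to the
  acceleration peak at the angular-speed minimum; ski contact from the
  last pitch-rate peak before, to the last negative vertical-acceleration
  peak after, the low-angular-velocity ground phase.
* **Power partition** — pole power `P_pole = F⃗_pole · v⃗_CoM` per side from
  axial force and marker-derived centre-of-mass velocity; work rate
  `P_cycle = m g v (sin θ + μ cos θ)` (μ = 0.016); ski power as the
  residual `P_ski = P_cycle − P_pole`, with `%P_pole + %P_ski = 100`
  exactly.
* **Fluctuation statistics** — terrain-dependent fluctuation
  `TDF = mean over laps 2–7 of (%PeakVal − %MinVal)` and time-dependent
  change `TDC = %MeanVal(late lap) − %MeanVal(early lap)`, on per-second
  %-of-max series.
* **Statistics** — Shapiro–Wilk-gated paired t / Wilcoxon signed-rank
  tests and two-way repeated-measures ANOVA (lap × segment, subject as
  repeated factor) with Tukey post-hoc pairs.

Because raw recordings of this kind are not public, the package ships a
first-class synthetic session generator (`generate_session()`) that
produces every stream plus ground truth (cycle boundaries, labels, contact
events, true CoM velocity, per-cycle power, clock offsets), making every
pipeline stage testable. See the methods vignette
(`vignettes/skifuse-methods.Rmd`) for the model and all tunable parameters.

## Worked example

```r
library(skifuse)

protocol <- default_protocol()          # 7 x 3 min laps, 4 segments
session_distance_and_speed(protocol, "HI")[1:2]
#> $distance_km
#> [1] 7.5
#> $mean_speed_kmh
#> [1] 21.3

session <- generate_session(protocol, "HI", seed = 1)   # all streams + truth
res <- analyze_session(session)                          # full pipeline
m <- res$master                                          # 1260 rows, 1 Hz

sprintf("TDF %%HR: %.1f pp, TDC %%HR (lap 7 - lap 2): %.1f pp",
        tdf(m$pct_hr, protocol), tdc(m$pct_hr, protocol, c(2, 7)))
#> [1] "TDF %HR: 11.4 pp, TDC %HR (lap 7 - lap 2): 5.3 pp"

tdc(m$pct_p_pole, protocol, c(1, 7))    # shift toward ski power, %-points
#> [1] -7.3

aggregate_by(m, c("segment", "subtech"), variables = "pct_p_pole")
#>   segment subtech   variable mean   sd n_seconds
#> 1       3      G2 pct_p_pole 42.1 3.54       168
#> 2       1      G3 pct_p_pole 60.7 2.99       420
#> 3       3      G3 pct_p_pole 29.9 1.66       112
#> 4       2      G4 pct_p_pole 68.2 3.49       350
```

Reading the output: the HI session fluctuates 11.4 %-points of HRmax
within a lap purely from terrain, heart rate drifts 5.3 %-points upward
between lap 2 and lap 7, and by lap 7 the skier derives 7.3 %-points more
of the total power from ski push-offs than in lap 1. The pole share of
power depends on gear and incline: highest for G4 on the flat (68 %),
lowest for G2/G3 on the steep ascent (42 %/30 %).

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/skifuse.R generate  --intensity LI --seed 1 --out session_dir
Rscript inst/scripts/skifuse.R classify  --session session_dir --model model.rds --out cycles.csv
Rscript inst/scripts/skifuse.R summarize --master master.csv --out summary_dir
```

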