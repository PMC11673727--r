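# ibaemg

Quantifying physical human–exoskeleton interaction (pHEI) from paired
surface-EMG recordings.

Occupational back-support exoskeletons are evaluated by comparing the muscle
activity a worker produces with the device (**Exo**) against the same task
performed without it (**NoExo**). Point metrics — the percentage variation of
the mean or maximum activation — collapse the whole task into one number and
say nothing about *when* the device helps or hinders. `ibaemg` implements an
integrated-EMG (iEMG) based analysis that keeps the time dimension: a
per-sample interaction trend whose positive excursions mark assistance and
negative excursions resistance, summarized by three indices per task phase.
It is aimed at exoskeleton developers and movement scientists who need to
diagnose control-strategy timing, not just report an overall reduction.

## The method

Both conditions are processed identically (fourth-order Butterworth
band-pass 30–400 Hz, rectification, fourth-order 2.5 Hz low-pass, 95th
percentile MVC normalization), segmented into task phases by thresholds on
the trunk/hip rotation angle, and resampled so each phase has the same
number of samples in both conditions. On the aligned envelopes, the
interaction trend over an analysis segment (full task or a single phase) is

    I_Trend(i) = 100 · (EMG_NoExo(i) − EMG_Exo(i)) / Σ_j EMG_NoExo(j)

where the sum runs over the same segment, so each sample is expressed in
percent of the baseline neural energy that segment requires. The indices are

    AII = Σ I_Trend(i)   over samples with I_Trend(i) ≥ 0   (assistance)
    RII = | Σ I_Trend(i) |  over samples with I_Trend(i) < 0  (resistance)
    OII = AII − RII                                           (overall)

For a uniformly sampled segment, OII is identical to the mean-based
percentage variation `100·(Mean_NoExo − Mean_Exo)/Mean_NoExo` — the package
verifies this identity to 1e-9 on thousands of randomized pairs — while AII
and RII additionally separate the assistive and resistive epochs that the
mean conflates. The classical mean/max percentage-variation indices are
provided alongside, together with a diagnostic that flags the common
failure mode where the two conditions peak in different task phases and the
full-task max comparison becomes meaningless.

## Worked example

The package ships a synthetic-trial generator with exact ground truth: a
bend–hold–rise trunk task whose Exo envelope is the NoExo envelope scaled by
a known per-phase assistance ratio α (OII ground truth `100·(1−α)` per
phase). Below, α = (0.7, 0.6, 0.9), i.e. true per-phase OII = (30, 40, 10):

```r
library(ibaemg)

spec  <- trial_spec(alpha = c(bending = 0.7, position_holding = 0.6,
                              rising_up = 0.9), seed = 3)
trial <- simulate_trial(spec)               # raw EMG + angle + MVC + truth

env_no <- process_emg(trial$raw$noexo, trial$raw$mvc)
env_ex <- process_emg(trial$raw$exo,   trial$raw$mvc)
phases <- detect_phases(trial$angle)        # threshold segmentation
pair   <- align_pair(env_no, env_ex, phases, phases)
analyze_pair(pair)
```

```
<iba_analysis>
      scope            phase n_samples    aii    rii    oii mean_pv
1 full_task        full_task      5000 19.158 0.5612 18.596  18.596
2 per_phase          upright      1000 27.297 0.2255 27.072  27.072
3 per_phase          bending      1000 29.913 0.0000 29.913  29.913
4 per_phase position_holding      1000 39.561 0.0000 39.561  39.561
5 per_phase        rising_up      1000  6.979 1.1302  5.849   5.849
6 per_phase          upright      1000  6.942 1.2032  5.739   5.739
```

The per-phase OIIs recover the programmed 30/40/10 within single-trial
noise (averaging across seeds tightens this to a fraction of a percentage
point — that experiment is in the test suite), `oii` equals `mean_pv` in
every row, and the first detected "upright" segment shows elevated OII
because the device in the simulation engages below the 15° detection
threshold. The peak diagnostic on the same pair prints

```
<peak_mismatch> NoExo peak in 'bending', Exo peak in 'rising_up': MISMATCH
(full-task MaxPV unreliable)
```

so `pv_table(pair)` marks the full-task max row `reliable = FALSE`.

For whole studies, `run_pipeline()` consumes a manifest CSV (subject ×
device × muscle → file paths), logs every configured default, skips failing
cells with a recorded reason, and `aggregate_indices()` averages
per-subject indices per device × muscle × phase. A thin command-line
wrapper with `simulate`, `preprocess`, `segment`, `analyze`, and `report`
subcommands lives in `inst/cli/iba.R`.

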