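# Deposited per-trial source data (not redistributed)

Two acceptance checks in `tests/testthat/test-acceptance.R` reproduce the
published Experiment-3 model comparison and the behavioral descriptives
from the deposited per-trial source-data files of the original study.
Those files are not redistributable with this package, so the checks fail
("red") in an offline environment.

To run them, convert the deposited spreadsheets ("Figure 1/2/5—source
data 1") to this package's trial CSV dialect and place them here as:

- `exp1_trials.csv`
- `exp2_trials.csv`
- `exp3_trials.csv`

Required columns (one row per trial):

| column      | content                                            |
|-------------|----------------------------------------------------|
| participant | participant id, unique within the file             |
| trial       | trial index within participant                     |
| cycle       | movement cycle (one reach per target per cycle)    |
| block       | `baseline_nofb`, `baseline_veridical`, `clamp`, `zero_clamp`, `washout_nofb`, `washout_veridical` |
| target_deg  | target location, degrees                           |
| clamp_dir   | `CW` or `CCW` (the deposited files are pre-flipped: use `CW` everywhere in that case) |
| hand_angle  | hand angle at peak radial velocity, degrees        |
| group       | condition label: `hit` / `straddle` / `miss` (Exp 1-2), `straddle_to_hit` / `hit_to_straddle` (Exp 3) |
| rt, mt      | optional, milliseconds                             |

`read_trials()` can remap foreign column names via its `column_map`
argument.
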