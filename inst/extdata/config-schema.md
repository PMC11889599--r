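# Simulation configuration schema

`run_grid()` and the `platformsim` command-line wrapper accept a YAML or
JSON file with the following keys. Every combination of `design`,
`scenario`, `rp`, and `accrual_mean` becomes one simulation cell with its
own reproducible random stream derived from `seed`.

| key            | type              | default | meaning                                                                 |
|----------------|-------------------|---------|-------------------------------------------------------------------------|
| `design`       | string or list    | (required) | Design labels, e.g. `stand-alone`, `MAT(1:1:1:1:1)`, `MAT(1:1:1:1:2)`, `PT(1:1:1:1:1)`, `PT(1:1:1:1:k)`, `PT-irr(1:1:1:1:1)`, `PT-irr(1:1:1:1:k)` (3- and 5-drug analogues alike). |
| `n_drugs`      | integer           | 4       | Number of drug arms (3, 4, or 5); must agree with the ratio strings.     |
| `per_drug_cap` | integer           | 435     | Planned patients per drug arm.                                           |
| `accrual_mean` | number or list    | 200     | Mean total patients arriving per month (Poisson).                        |
| `rp`           | number or list    | 0.10    | True placebo mortality rate(s); studied grid 0.05-0.15 in steps of 0.025.|
| `scenario`     | integer or list   | 5       | Scenario index 1..(n_drugs + 1); scenario s has s - 1 effective drugs.   |
| `n_reps`       | integer           | 10000   | Simulation replicates per cell.                                          |
| `alpha`        | number in (0, 1)  | 0.05    | Two-sided significance level per drug comparison.                        |
| `seed`         | integer           | 1       | Master seed; per-cell seeds are derived deterministically from it.       |

Unknown keys are rejected. Example (`example-config.yaml`):

```yaml
design:
  - "PT(1:1:1:1:1)"
  - "PT(1:1:1:1:k)"
n_drugs: 4
accrual_mean: [100, 200, 300, 400]
rp: [0.075, 0.10, 0.125, 0.15]
scenario: [2, 3, 4, 5]
n_reps: 1000
alpha: 0.05
seed: 20250217
```

Outputs written by `run_grid(config, out_dir)`:

- `oc.csv` — tidy long table: design, scenario, rp, accrual_mean, n_reps,
  metric, drug, estimate, mc_se.
- `cells.csv` — one row per cell with headline summaries and the cell seed.
- `manifest.json` — configuration snapshot, package version, per-cell
  seeds, wall time, output paths. The same configuration reproduces the
  CSVs byte for byte.
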