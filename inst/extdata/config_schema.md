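# Simulation configuration schema

A configuration file is YAML (or JSON) with up to five blocks. Every
block and every field is optional; omitted fields take the package
defaults (shown in `default_config.yaml` next to this file). Units in
files are the conventional bedside ones; the package converts to its
internal cmH2O / L / s system on load.

## `lung`

Either a preset:

```yaml
lung:
  preset: healthy        # fibrosis | healthy | emphysema
  peep_cmH2O: 8          # optional baseline override
```

or explicit Windkessel parameters:

| field         | unit        | default | meaning                          |
|---------------|-------------|---------|----------------------------------|
| `R_cmH2O_s_L` | cmH2O.s/L   | 3       | airway resistance                |
| `C_mL_cmH2O`  | mL/cmH2O    | 30      | lung compliance (warned below 5) |
| `peep_cmH2O`  | cmH2O       | 8       | baseline end-expiratory pressure |
| `label`       | text        | custom  | condition name                   |

## `diverter`

Reduced-order oscillator constants. Defaults are the frozen
calibration; change them only to re-characterize the device.

| field                      | unit      | meaning                                    |
|----------------------------|-----------|--------------------------------------------|
| `flow_L_min`               | L/min     | source flow (default 30)                   |
| `eta_insp`                 | (0,1]     | fraction of source flow reaching the lung  |
| `R_EC_open`, `R_EC_span`   | cmH2O.s/L | exhaust screw resistance law               |
| `delta_EC`                 | –         | exhaust screw taper regularizer            |
| `R_SC_open`, `R_SC_span`   | cmH2O.s/L | side-channel leak law (documentation)      |
| `P_high_base`, `k_SC`, `k_FC` | cmH2O  | upper threshold map P_high_base + k_SC d_SC − k_FC d_FC |
| `P_low_base`, `m_SC`, `m_FC`  | cmH2O  | lower threshold map                        |

## `screws`

Occlusion fractions in [0, 1] (0 = open, 1 = closed):

```yaml
screws: {EC: 0.5, FC: 0.5, SC: 0.5}
```

## `trigger`

| field             | unit  | meaning                                        |
|-------------------|-------|------------------------------------------------|
| `enabled`         | bool  | patient effort on/off (default off)            |
| `interval_s`      | s     | effort every T seconds (default 4)             |
| `times_s`         | s     | explicit effort start times (overrides interval) |
| `amplitude_cmH2O` | cmH2O | effort magnitude (default 3; bench profile 5.5) |
| `tau_s`           | s     | first-order time constant (default R.C of the lung) |

## `sim`

| field               | unit | meaning                              |
|---------------------|------|--------------------------------------|
| `dt_s`              | s    | integration step (default 0.001)     |
| `duration_s`        | s    | horizon (default 60; >= 10 dt)       |
| `transient_discard` | –    | start-up cycles dropped by analytics |
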