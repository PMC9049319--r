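# Example coupled-run configuration: a 3 ml idealized cylinder sealed at
# +10 C, surroundings ramped at 0.4 C/min to -10 C and held.
geometry:
  kind: axisym2d
  radius_m: 0.00585
  height_m: 0.0292
  wall_thickness_m: 0
schedule:
  - {time_s: 0, T_C: 10}
  - {time_s: 3000, T_C: -10}
h: 900
T0_C: 10
seal_T_C: 10
dt_s: 2.5
resolution: 16
max_time_s: 4800
mechanics_level: 1
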