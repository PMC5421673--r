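duration: 40.0
rate: 100.0
hip_amplitude_deg: 20.0
hip_omega: 1.5707963
rise_time: 0.3
emg_noise_sd: 0.02
process_noise:
  angle: 0.001
  rate: 0.005
  activation: 0.002
  force: 0.002
measurement_noise: 0.005236
integrator: euler
substeps: 10.0
blocks:
- muscle: SOL
  level: 0.15
  start: 0.0
  duration: 5.0
- muscle: GAS
  level: 0.1
  start: 0.0
  duration: 5.0
- muscle: TA
  level: 0.2
  start: 10.0
  duration: 5.0
- muscle: RF
  level: 0.2
  start: 20.0
  duration: 5.0
- muscle: VM
  level: 0.15
  start: 20.0
  duration: 5.0
- muscle: HAMS
  level: 0.2
  start: 20.0
  duration: 5.0
- muscle: TA
  level: 0.25
  start: 30.0
  duration: 5.0
- muscle: SOL
  level: 0.18
  start: 30.0
  duration: 5.0
- muscle: GAS
  level: 0.1
  start: 30.0
  duration: 5.0
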