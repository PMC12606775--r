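emg_rate: 2000.0
imu_rate: 2000.0
mocap_rate: 200.0
node_count: 101
alpha: 0.05
conditions:
- condition: OG
  speed: ~
  water_depth: none
  has_mocap: no
- condition: TM
  speed: 1.7
  water_depth: none
  has_mocap: yes
- condition: TM80
  speed: 1.4
  water_depth: none
  has_mocap: yes
- condition: WT80
  speed: 1.4
  water_depth: mid-metatarsal
  has_mocap: yes
strides_per_condition: 32
muscles:
- BF
- GM
- TFL
- LD_left
- LD_right
reference_condition: OG
seed: 1
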