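participant:
  id: EXAMPLE
  mass_kg: 65.67
  height_m: 1.72
  valgus_deg: 3.0
  onerm_kg: 78.8
  group: normal
  segment_scales:
    foot: 1.0
    shank: 1.0
    thigh: 1.0
    pelvis: 1.0
segments:
  foot:
    mass: 0.899679
    length: 0.26144
    com_frac: 0.5
    ankle_height: 0.06708
    com_local:
    - 0.0496736
    - 0.03354
    - 0.0
    inertia:
    - 0.0055344
    - 0.0016603
    - 0.0055344
  shank:
    mass: 2.843511
    length: 0.42312
    com_frac: 0.433
    com_local:
    - 0.0
    - 0.239909
    - 0.0
    inertia:
    - 0.0458168
    - 0.013745
    - 0.0458168
  thigh:
    mass: 9.298872
    length: 0.4214
    com_frac: 0.433
    com_local:
    - 0.0
    - 0.2389338
    - 0.0
    inertia:
    - 0.1486147
    - 0.0445844
    - 0.1486147
  pelvis:
    mass: 52.627938
    length: 0.8084
    com_frac: 0.36
    com_local:
    - 0.0
    - 0.516
    - 0.0
    inertia:
    - 3.0953622
    - 0.9286087
    - 3.0953622
dofs:
- subtalar_supination
- ankle_dorsiflexion
- knee_flexion
- knee_adduction
- knee_rotation
- hip_flexion
- hip_adduction
- hip_rotation
dof_axis:
  subtalar_supination: x
  ankle_dorsiflexion: z
  knee_flexion: z
  knee_adduction: x
  knee_rotation: 'y'
  hip_flexion: z
  hip_adduction: x
  hip_rotation: 'y'
dof_mech_sign:
  subtalar_supination: 1.0
  ankle_dorsiflexion: -1.0
  knee_flexion: 1.0
  knee_adduction: 1.0
  knee_rotation: 1.0
  hip_flexion: -1.0
  hip_adduction: 1.0
  hip_rotation: 1.0
muscles:
  rectus_femoris:
    fmax: 1200.0
    crosses_knee: yes
    knee_axial: 0.45
    arms:
      knee_flexion:
      - -0.04
      - -5.0e-05
      knee_adduction: -0.004
  vasti:
    fmax: 7000.0
    crosses_knee: yes
    knee_axial: 0.45
    arms:
      knee_flexion: -0.042
      knee_adduction: -0.012
  biceps_femoris:
    fmax: 800.0
    crosses_knee: yes
    knee_axial: 0.45
    arms:
      knee_flexion: 0.035
      hip_flexion: -0.055
      knee_adduction: -0.006
  gluteus:
    fmax: 3000.0
    crosses_knee: no
    arms:
      hip_flexion: -0.06
      hip_adduction: -0.045
      hip_rotation: -0.02
  adductors:
    fmax: 1200.0
    crosses_knee: no
    arms:
      hip_adduction: 0.035
      hip_flexion: 0.01
  tibialis_anterior:
    fmax: 900.0
    crosses_knee: no
    arms:
      ankle_dorsiflexion: 0.033
  gastrocnemius:
    fmax: 1500.0
    crosses_knee: yes
    knee_axial: 0.45
    arms:
      ankle_dorsiflexion: -0.048
      knee_adduction: -0.008
  soleus:
    fmax: 3500.0
    crosses_knee: no
    arms:
      ankle_dorsiflexion: -0.038
  peroneus:
    fmax: 1200.0
    crosses_knee: no
    arms:
      subtalar_supination: -0.035
  hip_rotators:
    fmax: 400.0
    crosses_knee: no
    arms:
      hip_rotation: 0.025
markers:
  RHEE:
    segment: calcaneus
    offset:
    - -0.06536
    - 0.03
    - 0.0
  RCAL:
    segment: calcaneus
    offset:
    - -0.0705888
    - 0.09
    - 0.01
  RTOE:
    segment: foot
    offset:
    - 0.1882368
    - 0.02
    - 0.01
  RMT5:
    segment: foot
    offset:
    - 0.117648
    - 0.02
    - 0.05
  RANK:
    segment: shank
    offset:
    - 0.0
    - 0.02
    - 0.045
  RMMA:
    segment: shank
    offset:
    - 0.0
    - 0.03
    - -0.04
  RTIB:
    segment: shank
    offset:
    - 0.02
    - 0.1777104
    - 0.04
  RSHN:
    segment: shank
    offset:
    - 0.03
    - 0.2792592
    - 0.01
  RKNE:
    segment: thigh
    offset:
    - 0.0
    - 0.008428
    - 0.055
  RMKN:
    segment: thigh
    offset:
    - 0.0
    - 0.012642
    - -0.05
  RTHI:
    segment: thigh
    offset:
    - 0.02
    - 0.18963
    - 0.05
  RTHF:
    segment: thigh
    offset:
    - 0.05
    - 0.29498
    - 0.0
  RASI:
    segment: pelvis
    offset:
    - 0.06
    - 0.1
    - 0.02
  LASI:
    segment: pelvis
    offset:
    - 0.06
    - 0.1
    - -0.2
  SACR:
    segment: pelvis
    offset:
    - -0.1
    - 0.12
    - -0.09
  TRNK:
    segment: pelvis
    offset:
    - -0.04
    - 0.2064
    - -0.09
tibial_plateau_width: 0.08
barbell_height: 0.602
weight_share: 0.5
gravity: 9.81
scaled: no
scale_factors:
  foot: 1.0
  shank: 1.0
  thigh: 1.0
  pelvis: 1.0
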