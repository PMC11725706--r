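# Riojasuchus tenuisceps hindlimb joint ROM limits, transcribed from the
# published figure captions (degrees; extension/abduction/external-LAR
# positive). Segments carry no meshes: this fixture records the published
# judgment-based limits, not scan geometry.
name: riojasuchus_rom
segments:
  - name: pelvis
  - name: femur
  - name: crus
  - name: pes
  - name: toe3
joints:
  - name: hip
    parent: pelvis
    child: femur
    origin: [0.0, 0.0, 0.0]
    dof: [x, y, z]
    rom:
      z: [-65.0, 55.0]    # flexion -65 to extension 55
      y: [-10.0, 70.0]    # abduction -10 to adduction 70 (as printed)
      x: [-50.0, 50.0]    # internal -50 to external 50 long-axis rotation
  - name: knee
    parent: femur
    child: crus
    origin: [0.0, 0.0, -0.179]
    dof: [z]
    rom:
      z: [-110.0, 0.0]    # flexion -110; extension limit 0
  - name: ankle
    parent: crus
    child: pes
    origin: [0.0, 0.0, -0.320]
    dof: [z]
    rom:
      z: [-50.0, 30.0]    # flexion -50 to extension 30 (span 80)
  - name: mtp3
    parent: pes
    child: toe3
    origin: [0.08, 0.0, -0.320]
    dof: [z]
    rom:
      z: [-80.0, 50.0]    # plantarflexion -80 to dorsiflexion 50
landmarks:
  acetabulum:
    segment: pelvis
    point: [0.0, 0.0, 0.0]
  glenoid:
    segment: pelvis
    point: [0.355, 0.0, 0.0]
chains:
  hindlimb:
    joints: [hip, knee, ankle]
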