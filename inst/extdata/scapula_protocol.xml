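<?xml version="1.0" encoding="UTF-8"?>
<PersonalizationSettings version="1">
  <Task name="scapulothoracic_stage" rate="20" maxiter="40" marker_file="all_motions.trc">
    <JointParameter joint="scapulothoracic" frame="parent" component="rx"/>
    <JointParameter joint="scapulothoracic" frame="parent" component="ry"/>
    <JointParameter joint="scapulothoracic" frame="parent" component="rz"/>
    <JointParameter joint="scapulothoracic" frame="parent" component="tx"/>
    <JointParameter joint="scapulothoracic" frame="parent" component="ty"/>
    <JointParameter joint="scapulothoracic" frame="parent" component="tz"/>
    <JointParameter joint="scapulothoracic" frame="child" component="tx"/>
    <JointParameter joint="scapulothoracic" frame="child" component="ty"/>
    <JointParameter joint="scapulothoracic" frame="child" component="tz"/>
    <JointParameter joint="scapulothoracic" frame="child" component="rx"/>
    <JointParameter joint="scapulothoracic" frame="child" component="ry"/>
    <JointParameter joint="scapulothoracic" frame="child" component="rz"/>
  </Task>
  <Task name="scapulothoracic_full" maxiter="15" marker_file="all_motions.trc">
    <JointParameter joint="scapulothoracic" frame="parent" component="rx"/>
    <JointParameter joint="scapulothoracic" frame="parent" component="ry"/>
    <JointParameter joint="scapulothoracic" frame="parent" component="rz"/>
    <JointParameter joint="scapulothoracic" frame="parent" component="tx"/>
    <JointParameter joint="scapulothoracic" frame="parent" component="ty"/>
    <JointParameter joint="scapulothoracic" frame="parent" component="tz"/>
    <JointParameter joint="scapulothoracic" frame="child" component="tx"/>
    <JointParameter joint="scapulothoracic" frame="child" component="ty"/>
    <JointParameter joint="scapulothoracic" frame="child" component="tz"/>
    <JointParameter joint="scapulothoracic" frame="child" component="rx"/>
    <JointParameter joint="scapulothoracic" frame="child" component="ry"/>
    <JointParameter joint="scapulothoracic" frame="child" component="rz"/>
  </Task>
</PersonalizationSettings>
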