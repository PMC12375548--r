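<?xml version="1.0" encoding="UTF-8"?>
<PersonalizationSettings version="1">
  <Task name="glenohumeral" rate="20" maxiter="30" marker_file="all_motions.trc">
    <JointParameter joint="glenohumeral" frame="parent" component="tx"/>
    <JointParameter joint="glenohumeral" frame="parent" component="ty"/>
    <JointParameter joint="glenohumeral" frame="parent" component="tz"/>
    <JointParameter joint="glenohumeral" frame="child" component="tx"/>
    <JointParameter joint="glenohumeral" frame="child" component="ty"/>
    <JointParameter joint="glenohumeral" frame="child" component="tz"/>
  </Task>
  <Task name="acromioclavicular" rate="20" maxiter="30" marker_file="all_motions.trc">
    <BodyScale body="clavicle" axis="x"/>
    <ConstraintPoint constraint="1" side="b" axis="x"/>
    <ConstraintPoint constraint="1" side="b" axis="y"/>
    <ConstraintPoint constraint="1" side="b" axis="z"/>
  </Task>
  <Task name="sternoclavicular" rate="20" maxiter="30" marker_file="all_motions.trc">
    <JointParameter joint="sternoclavicular" frame="parent" component="rx"/>
    <JointParameter joint="sternoclavicular" frame="parent" component="ry"/>
    <JointParameter joint="sternoclavicular" frame="parent" component="rz"/>
  </Task>
  <Task name="scapulothoracic_parent" rate="20" maxiter="30" marker_file="all_motions.trc">
    <JointParameter joint="scapulothoracic" frame="parent" component="tx"/>
    <JointParameter joint="scapulothoracic" frame="parent" component="ty"/>
    <JointParameter joint="scapulothoracic" frame="parent" component="tz"/>
  </Task>
  <Task name="scapulothoracic_child" rate="20" maxiter="30" marker_file="all_motions.trc">
    <JointParameter joint="scapulothoracic" frame="child" component="tx"/>
    <JointParameter joint="scapulothoracic" frame="child" component="ty"/>
    <JointParameter joint="scapulothoracic" frame="child" component="tz"/>
    <JointParameter joint="scapulothoracic" frame="child" component="rx"/>
    <JointParameter joint="scapulothoracic" frame="child" component="ry"/>
    <JointParameter joint="scapulothoracic" frame="child" component="rz"/>
  </Task>
  <Task name="combined" maxiter="15" marker_file="all_motions.trc">
    <JointParameter joint="glenohumeral" frame="parent" component="tx"/>
    <JointParameter joint="glenohumeral" frame="parent" component="ty"/>
    <JointParameter joint="glenohumeral" frame="parent" component="tz"/>
    <JointParameter joint="glenohumeral" frame="child" component="tx"/>
    <JointParameter joint="glenohumeral" frame="child" component="ty"/>
    <JointParameter joint="glenohumeral" frame="child" component="tz"/>
    <BodyScale body="clavicle" axis="x"/>
    <ConstraintPoint constraint="1" side="b" axis="x"/>
    <ConstraintPoint constraint="1" side="b" axis="y"/>
    <ConstraintPoint constraint="1" side="b" axis="z"/>
    <JointParameter joint="sternoclavicular" frame="parent" component="rx"/>
    <JointParameter joint="sternoclavicular" frame="parent" component="ry"/>
    <JointParameter joint="sternoclavicular" frame="parent" component="rz"/>
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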