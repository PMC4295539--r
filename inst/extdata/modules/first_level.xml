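<interface>
  <currenttask name="first_level" domain="subject"
               desc="First-level GLM: fit events and contrasts per subject" modality="MRI">
    <qsub><memoryBase>0.5</memoryBase><timeBase>0.5</timeBase></qsub>
    <permanenceofoutput>3</permanenceofoutput>
    <hrf>boxcar</hrf>
    <tr>2</tr>
    <inputstreams>
      <stream>epi</stream>
      <stream>realignment_parameter</stream>
    </inputstreams>
    <outputstreams>
      <stream>con</stream>
      <stream>beta</stream>
      <stream>firstlevel_stats</stream>
    </outputstreams>
  </currenttask>
</interface>
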