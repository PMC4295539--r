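<interface>
  <currenttask name="realign" domain="session"
               desc="Motion-correct a series by integer translation search" modality="MRI">
    <qsub><memoryBase>0.3</memoryBase><timeBase>0.5</timeBase></qsub>
    <permanenceofoutput>1</permanenceofoutput>
    <max_shift>3</max_shift>
    <inputstreams><stream>epi</stream></inputstreams>
    <outputstreams>
      <stream>realignment_parameter</stream>
      <stream>meanepi</stream>
      <stream>epi</stream>
    </outputstreams>
  </currenttask>
</interface>
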