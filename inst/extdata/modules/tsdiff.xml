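<interface>
  <currenttask name="tsdiff" domain="session"
               desc="Successive-volume difference quality control" modality="MRI">
    <permanenceofoutput>2</permanenceofoutput>
    <outlier_mult>10</outlier_mult>
    <inputstreams><stream>epi</stream></inputstreams>
    <outputstreams><stream>qc_timediff</stream></outputstreams>
  </currenttask>
</interface>
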