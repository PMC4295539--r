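<interface>
  <currenttask name="passthrough" domain="session"
               desc="Copy the epi stream unchanged (test module)" modality="MRI">
    <permanenceofoutput>0</permanenceofoutput>
    <fail>false</fail>
    <inputstreams><stream>epi</stream></inputstreams>
    <outputstreams><stream>epi</stream></outputstreams>
  </currenttask>
</interface>
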