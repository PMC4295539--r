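<tasklist>
  <initialisation>
    <module><name>check_parameters</name></module>
  </initialisation>
  <main>
    <module><name>import_structural</name></module>
    <module><name>import_epi</name></module>
    <module><name>realign</name></module>
    <module><name>tsdiff</name></module>
    <module><name>smooth</name></module>
    <module><name>first_level</name></module>
    <module><name>second_level</name></module>
  </main>
</tasklist>
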