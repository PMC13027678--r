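concept	surface_form
depressive_state	depressive state
depressive_state	depressed mood
depressive_state	low mood
depressive_state	depression
depressive_state	dysphoria
depressive_state	melancholia
depressive_state	depressive episode
depressive_state	depressive symptoms
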