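(TITLE:"database" OR ABSTRACT:"database" OR ABSTRACT:"resource") AND (ABSTRACT:"http" OR ABSTRACT:"www") AND (LANG:"eng") AND (PUB_YEAR:[2011 TO 2021])
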