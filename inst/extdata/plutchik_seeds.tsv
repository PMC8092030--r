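emotion	term
anger	angry
anger	furious
anger	rage
anger	outraged
anger	irritated
anger	mad
sadness	sad
sadness	grief
sadness	sorrow
sadness	miserable
sadness	heartbroken
sadness	depressed
disgust	disgusted
disgust	revolting
disgust	gross
disgust	repulsive
disgust	vile
disgust	sickened
fear	scared
fear	afraid
fear	terrified
fear	panic
fear	dread
fear	frightening
joy	happy
joy	delighted
joy	cheerful
joy	glad
joy	thrilled
joy	joyful
surprise	surprised
surprise	astonished
surprise	shocked
surprise	unexpected
surprise	stunned
surprise	startling
trust	trust
trust	faith
trust	reliable
trust	confident
trust	assured
trust	dependable
anticipation	anticipation
anticipation	expecting
anticipation	hopeful
anticipation	eager
anticipation	awaiting
anticipation	keen
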